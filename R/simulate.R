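#' Configuration for the synthetic dual-run generator
#'
#' Describes a simulated tissue-microarray slide profiled with two probe
#' panels in two sequential decoding runs of the same section: a small
#' high-sensitivity custom panel ("V1", 480 genes) and a large discovery
#' panel ("Prime", 5001 genes) sharing 239 target genes. Defaults follow the
#' study conditions the package models: 17 rectangular sample (TMA core)
#' regions, per-cell expected transcript totals of 125 (V1) and 115 (Prime)
#' matching the observed median transcripts per cell of the solo runs, and a
#' multiplicative sensitivity attenuation of 0.8 applied to the Prime rates
#' of shared genes in the dual run (the competitive-binding effect under
#' study).
#'
#' @param n_cells number of cells on the slide.
#' @param n_samples number of rectangular sample (TMA core) regions.
#' @param n_genes_v1,n_genes_prime,n_overlap panel sizes and the number of
#'   genes targeted by both panels (`n_overlap <= min(panel sizes)`).
#' @param mean_counts_v1,mean_counts_prime expected transcripts per cell
#'   emitted by each chemistry (before any QC).
#' @param prime_overlap_attenuation multiplier in `[0, 1]` applied to the
#'   Prime-run rates of shared genes (1 = solo-run behaviour, < 1 = the dual
#'   run's sensitivity loss).
#' @param true_transform `affine_transform` mapping the first run's frame
#'   into the second run's frame (the cassette re-seating offset).
#' @param background_rate expected unassigned transcripts per square
#'   micrometer of cell-free slide area.
#' @param qv_fail_fraction fraction of transcripts drawn from the
#'   low-quality (QV < 20) mixture component.
#' @param seed integer seed for cells, counts, placement and noise.
#' @param expression_seed integer seed for per-gene abundances and
#'   secreted-gene identity only. Two configs sharing `expression_seed`
#'   simulate the same tissue (same per-gene rates) with independent cells,
#'   which is how solo and dual slides of one TMA are emulated.
#' @param size_factor_shape shape of the gamma per-cell size factors (mean
#'   1); Poisson counts mixed over these are negative-binomial marginally.
#' @param overlap_latent_sd standard deviation of the per-cell log-activity
#'   shared by the two panels' measurements of an overlapping gene; controls
#'   the cross-chemistry correlation.
#' @param gene_weight_sdlog lognormal sd of per-gene abundance weights.
#' @param nucleus_scale linear scale of the nucleus ring relative to the
#'   cell ring (area fraction is its square).
#' @param cell_radius,cell_spacing hexagonal cell circumradius and grid
#'   spacing, micrometers; `cell_spacing >= 2 * cell_radius` guarantees
#'   non-overlapping masks.
#' @param n_landmarks number of anchor pairs emitted (cell centroids).
#' @param landmark_sigma Gaussian jitter (um) on the fixed-frame anchor,
#'   emulating manual anchor placement error.
#' @param centroid_sigma jitter (um) on the second run's observed cell
#'   centroids, emulating independent re-segmentation.
#' @param secreted_fraction_v1,secreted_fraction_prime fraction of each
#'   panel's genes flagged as secreted (defaults 59/480 and 538/5001).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 400L,
                       n_samples = 17L,
                       n_genes_v1 = 480L,
                       n_genes_prime = 5001L,
                       n_overlap = 239L,
                       mean_counts_v1 = 125,
                       mean_counts_prime = 115,
                       prime_overlap_attenuation = 0.8,
                       true_transform = similarity_transform(
                         rotation_deg = 0.3, scale = 1.002,
                         translation = c(12, -7)),
                       background_rate = 0.05,
                       qv_fail_fraction = 0.1,
                       seed = 1L,
                       expression_seed = 1000L,
                       size_factor_shape = 3,
                       overlap_latent_sd = 0.5,
                       gene_weight_sdlog = 1.2,
                       nucleus_scale = 0.6,
                       cell_radius = 5,
                       cell_spacing = 13,
                       n_landmarks = 6L,
                       landmark_sigma = 0.5,
                       centroid_sigma = 0.2,
                       secreted_fraction_v1 = 59 / 480,
                       secreted_fraction_prime = 538 / 5001) {
  cfg <- list(n_cells = as.integer(n_cells), n_samples = as.integer(n_samples),
              n_genes_v1 = as.integer(n_genes_v1),
              n_genes_prime = as.integer(n_genes_prime),
              n_overlap = as.integer(n_overlap),
              mean_counts_v1 = mean_counts_v1,
              mean_counts_prime = mean_counts_prime,
              prime_overlap_attenuation = prime_overlap_attenuation,
              true_transform = true_transform,
              background_rate = background_rate,
              qv_fail_fraction = qv_fail_fraction,
              seed = as.integer(seed),
              expression_seed = as.integer(expression_seed),
              size_factor_shape = size_factor_shape,
              overlap_latent_sd = overlap_latent_sd,
              gene_weight_sdlog = gene_weight_sdlog,
              nucleus_scale = nucleus_scale,
              cell_radius = cell_radius, cell_spacing = cell_spacing,
              n_landmarks = as.integer(n_landmarks),
              landmark_sigma = landmark_sigma,
              centroid_sigma = centroid_sigma,
              secreted_fraction_v1 = secreted_fraction_v1,
              secreted_fraction_prime = secreted_fraction_prime)
  if (cfg$n_overlap > min(cfg$n_genes_v1, cfg$n_genes_prime))
    abort_dx("n_overlap exceeds a panel size", "duplexium_config_error")
  if (cfg$n_cells < 0L || cfg$n_samples < 1L)
    abort_dx("n_cells must be >= 0 and n_samples >= 1", "duplexium_config_error")
  if (cfg$mean_counts_v1 < 0 || cfg$mean_counts_prime < 0 ||
      cfg$background_rate < 0)
    abort_dx("rates must be nonnegative", "duplexium_config_error")
  if (cfg$prime_overlap_attenuation < 0 || cfg$prime_overlap_attenuation > 1)
    abort_dx("prime_overlap_attenuation must lie in [0, 1]", "duplexium_config_error")
  if (cfg$qv_fail_fraction < 0 || cfg$qv_fail_fraction > 1)
    abort_dx("qv_fail_fraction must lie in [0, 1]", "duplexium_config_error")
  if (!inherits(cfg$true_transform, "affine_transform"))
    abort_dx("true_transform must be an affine_transform", "duplexium_config_error")
  if (cfg$cell_spacing < 2 * cfg$cell_radius)
    abort_dx("cell_spacing must be at least twice cell_radius", "duplexium_config_error")
  if (cfg$nucleus_scale <= 0 || cfg$nucleus_scale >= 1)
    abort_dx("nucleus_scale must lie in (0, 1)", "duplexium_config_error")
  class(cfg) <- "sim_config"
  cfg
}

# panel gene names and secreted flags; driven by expression_seed only
make_panels <- function(config) {
  n_ov <- config$n_overlap
  ov <- sprintf("OVL%04d", seq_len(n_ov))
  v1_only <- sprintf("V1G%04d", seq_len(config$n_genes_v1 - n_ov))
  pr_only <- sprintf("PRG%04d", seq_len(config$n_genes_prime - n_ov))
  v1 <- panel_definition("V1", c(ov, v1_only))
  prime <- panel_definition("Prime", c(ov, pr_only))
  secreted <- with_seed(config$expression_seed + 1L, {
    s_v1 <- sample(v1$genes, round(config$secreted_fraction_v1 * length(v1$genes)))
    s_pr <- sample(prime$genes, round(config$secreted_fraction_prime * length(prime$genes)))
    list(v1 = sort(s_v1), prime = sort(s_pr))
  })
  list(v1 = v1, prime = prime, overlap = ov, secreted = secreted)
}

# shared per-gene abundance weights over the union of panel genes
gene_weights <- function(config, panels) {
  genes <- union(panels$v1$genes, panels$prime$genes)
  with_seed(config$expression_seed, {
    w <- stats::rlnorm(length(genes), meanlog = 0, sdlog = config$gene_weight_sdlog)
    names(w) <- genes
    w
  })
}

# count layer of the generator: cells x genes count matrices for one slide.
# Assumes the RNG is already seeded by the caller.
simulate_counts_impl <- function(config, panels, w) {
  n <- config$n_cells
  lam_v1 <- config$mean_counts_v1 * w[panels$v1$genes] / sum(w[panels$v1$genes])
  lam_pr <- config$mean_counts_prime * w[panels$prime$genes] / sum(w[panels$prime$genes])
  s <- stats::rgamma(n, shape = config$size_factor_shape,
                     rate = config$size_factor_shape)
  rate_v1 <- outer(s, lam_v1)
  rate_pr <- outer(s, lam_pr)
  n_ov <- config$n_overlap
  if (n_ov > 0L && n > 0L && config$overlap_latent_sd > 0) {
    sdl <- config$overlap_latent_sd
    lat <- matrix(exp(stats::rnorm(n * n_ov, -sdl^2 / 2, sdl)), n, n_ov)
    rate_v1[, seq_len(n_ov)] <- rate_v1[, seq_len(n_ov)] * lat
    rate_pr[, seq_len(n_ov)] <- rate_pr[, seq_len(n_ov)] * lat
  }
  if (n_ov > 0L)
    rate_pr[, seq_len(n_ov)] <- rate_pr[, seq_len(n_ov)] *
      config$prime_overlap_attenuation
  v1 <- matrix(stats::rpois(length(rate_v1), rate_v1),
               nrow = n, ncol = length(lam_v1),
               dimnames = list(NULL, panels$v1$genes))
  pr <- matrix(stats::rpois(length(rate_pr), rate_pr),
               nrow = n, ncol = length(lam_pr),
               dimnames = list(NULL, panels$prime$genes))
  list(v1 = v1, prime = pr, size_factors = s)
}

#' Simulate the count layer of a dual-chemistry slide
#'
#' Draws the cells x genes count matrices for both chemistries of one slide
#' without spatial placement: per-gene abundances are lognormal weights
#' shared across panels (drawn from `expression_seed`), each cell gets a
#' gamma size factor, overlapping genes get a per-cell log-normal activity
#' shared between the two panels, the Prime rates of overlapping genes are
#' multiplied by `prime_overlap_attenuation`, and counts are Poisson given
#' the rates (negative-binomial marginally). This is exactly the count model
#' inside [generate_dual_experiment()]; use it directly for statistical
#' calibration studies where geometry is irrelevant.
#'
#' @param config a [sim_config()].
#' @return list with `v1` and `prime` count matrices (cells x genes, gene
#'   names as dimnames), `size_factors`, and the `panels` list.
#' @export
simulate_panel_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panels <- make_panels(config)
  w <- gene_weights(config, panels)
  set.seed(config$seed)
  out <- simulate_counts_impl(config, panels, w)
  out$panels <- panels
  out
}

# hexagonal cell layout; returns list(masks, cells, centers, bbox)
make_geometry <- function(config) {
  n <- config$n_cells
  sp <- config$cell_spacing
  if (n == 0L) {
    return(list(masks = data.frame(cell_id = character(0), ring = character(0),
                                   vertex_index = integer(0), x = numeric(0),
                                   y = numeric(0), stringsAsFactors = FALSE),
                cells = data.frame(cell_id = character(0),
                                   sample_id = character(0),
                                   stringsAsFactors = FALSE),
                centers = matrix(numeric(0), 0, 2),
                bbox = c(0, 0, 0, 0)))
  }
  ncol_g <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1L) %/% ncol_g
  col <- (seq_len(n) - 1L) %% ncol_g
  cx <- (col + 0.5 * (row %% 2) + 0.5) * sp
  cy <- (row + 0.5) * sp * sqrt(3) / 2
  ids <- sprintf("cell_%05d", seq_len(n))

  rot <- stats::runif(n, 0, pi / 3)
  rad <- matrix(config$cell_radius * stats::runif(n * 6L, 0.85, 1), n, 6L)
  ang <- outer(rot, (0:5) * pi / 3, "+")
  vx <- cx + rad * cos(ang)
  vy <- cy + rad * sin(ang)
  ns <- config$nucleus_scale
  nvx <- cx + ns * rad * cos(ang)
  nvy <- cy + ns * rad * sin(ang)

  masks <- data.frame(
    cell_id = rep(rep(ids, each = 6L), 2L),
    ring = rep(c("cell", "nucleus"), each = 6L * n),
    vertex_index = rep(rep(1:6, times = n), 2L),
    x = c(as.numeric(t(vx)), as.numeric(t(nvx))),
    y = c(as.numeric(t(vy)), as.numeric(t(nvy))),
    stringsAsFactors = FALSE)

  bbox <- c(min(vx) - 1, min(vy) - 1, max(vx) + 1, max(vy) + 1)

  # rectangular sample regions on a near-square grid; trailing grid
  # rectangles fold into the last sample so every cell gets a label
  ncs <- ceiling(sqrt(config$n_samples))
  nrs <- ceiling(config$n_samples / ncs)
  ix <- pmin(ncs - 1L, floor((cx - bbox[1]) / (bbox[3] - bbox[1]) * ncs))
  iy <- pmin(nrs - 1L, floor((cy - bbox[2]) / (bbox[4] - bbox[2]) * nrs))
  region <- pmin(iy * ncs + ix + 1L, config$n_samples)
  cells <- data.frame(cell_id = ids,
                      sample_id = sprintf("S%02d", region),
                      stringsAsFactors = FALSE)
  list(masks = masks, cells = cells, centers = cbind(cx, cy), bbox = bbox)
}

# uniform points inside one polygon by rejection from its bounding box
sample_in_polygon <- function(n, vx, vy) {
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  xr <- range(vx); yr <- range(vy)
  while (length(need)) {
    m <- length(need)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    ok <- point_in_polygon(px, py, vx, vy)
    out[need[ok], ] <- cbind(px[ok], py[ok])
    need <- need[!ok]
  }
  out
}

# QV mixture: pass component >= 20, fail component < 20
draw_qv <- function(n, fail_fraction) {
  fail <- stats::runif(n) < fail_fraction
  qv <- numeric(n)
  qv[fail] <- pmin(19.9, pmax(0, stats::rnorm(sum(fail), 10, 3)))
  qv[!fail] <- pmin(50, pmax(20, stats::rnorm(sum(!fail), 40, 3)))
  qv
}

#' Generate a synthetic dual-chemistry experiment with known ground truth
#'
#' Builds one simulated slide: non-overlapping jittered-hexagon cell masks
#' (with nucleus rings) partitioned into rectangular sample regions, per-cell
#' per-gene counts from the model described in [simulate_panel_counts()],
#' transcript point placement uniform within each cell, a two-component QV
#' mixture exercising the QV >= 20 filter, uniform background transcripts
#' outside all cells (`cell_id = "UNASSIGNED"`), and a second decoding run
#' whose coordinates are the first run's positions mapped through
#' `true_transform`. Landmark anchor pairs (cell centroids, with optional
#' jitter) and the second run's observed centroids are emitted for
#' registration.
#'
#' Everything is deterministic given `config$seed` / `config$expression_seed`.
#'
#' @param config a [sim_config()].
#' @return A `dual_experiment` list: `config`, `panels`, `masks` (vertex
#'   table in the first run's frame), `cells` (cell_id, sample_id),
#'   `metrics` (per-cell geometry), `transcripts_run1` (V1 chemistry, first
#'   frame), `transcripts_run2` (Prime chemistry, second frame),
#'   `true_transform`, `landmarks`, `centroids_run2`, and sparse ground-truth
#'   count matrices `counts_v1` / `counts_prime` (cells x genes).
#' @export
generate_dual_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panels <- make_panels(config)
  w <- gene_weights(config, panels)
  set.seed(config$seed)
  counts <- simulate_counts_impl(config, panels, w)
  geom <- make_geometry(config)
  metrics <- if (nrow(geom$masks)) compute_cell_metrics(geom$masks) else
    data.frame(cell_id = character(0), cell_area = numeric(0),
               nucleus_area = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), stringsAsFactors = FALSE)

  place_run <- function(cmat, run_tag) {
    n <- config$n_cells
    recs <- vector("list", n + 1L)
    rings <- mask_rings(geom$masks)
    ring_key <- paste(vapply(rings, `[[`, "", "cell_id"),
                      vapply(rings, `[[`, "", "ring"))
    for (i in seq_len(n)) {
      cid <- geom$cells$cell_id[i]
      row <- cmat[i, ]
      nz <- which(row > 0L)
      if (!length(nz)) next
      genes <- rep(colnames(cmat)[nz], row[nz])
      nt <- length(genes)
      cring <- rings[[match(paste(cid, "cell"), ring_key)]]
      nring <- rings[[match(paste(cid, "nucleus"), ring_key)]]
      pos <- sample_in_polygon(nt, cring$x, cring$y)
      in_nuc <- point_in_polygon(pos[, 1], pos[, 2], nring$x, nring$y)
      recs[[i]] <- data.frame(gene = genes, x = pos[, 1], y = pos[, 2],
                              overlaps_nucleus = as.integer(in_nuc),
                              cell_id = cid,
                              sample_id = geom$cells$sample_id[i],
                              stringsAsFactors = FALSE)
    }
    # background: uniform over the cell-free slide area
    bbox <- geom$bbox
    free_area <- max(0, (bbox[3] - bbox[1]) * (bbox[4] - bbox[2]) -
                       sum(metrics$cell_area))
    n_bg <- if (config$n_cells > 0L)
      stats::rpois(1L, config$background_rate * free_area) else 0L
    if (n_bg > 0L) {
      got <- 0L
      bg <- matrix(NA_real_, n_bg, 2)
      while (got < n_bg) {
        m <- (n_bg - got) * 2L
        px <- stats::runif(m, bbox[1], bbox[3])
        py <- stats::runif(m, bbox[2], bbox[4])
        a <- assign_to_masks(cbind(px, py), geom$masks)
        free <- which(a$cell_id == "UNASSIGNED")
        take <- free[seq_len(min(length(free), n_bg - got))]
        if (length(take)) {
          bg[got + seq_along(take), ] <- cbind(px[take], py[take])
          got <- got + length(take)
        }
      }
      panel_genes <- if (run_tag == "v1") panels$v1$genes else panels$prime$genes
      recs[[n + 1L]] <- data.frame(
        gene = sample(panel_genes, n_bg, replace = TRUE),
        x = bg[, 1], y = bg[, 2],
        overlaps_nucleus = 0L, cell_id = "UNASSIGNED",
        sample_id = NA_character_, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
    if (is.null(df))
      df <- data.frame(gene = character(0), x = numeric(0), y = numeric(0),
                       overlaps_nucleus = integer(0), cell_id = character(0),
                       sample_id = character(0), stringsAsFactors = FALSE)
    df$qv <- draw_qv(nrow(df), config$qv_fail_fraction)
    df$transcript_id <- sprintf("%s_t%07d", run_tag, seq_len(nrow(df)))
    df$true_cell_id <- df$cell_id
    df[c("transcript_id", "gene", "x", "y", "qv", "overlaps_nucleus",
         "cell_id", "sample_id", "true_cell_id")]
  }

  t1 <- place_run(counts$v1, "v1")
  t2 <- place_run(counts$prime, "prime")
  t2 <- apply_transform(config$true_transform, t2)

  # anchors: spread cell centroids; fixed side in the second run's frame
  if (config$n_cells >= 1L && config$n_landmarks >= 1L) {
    k <- min(config$n_landmarks, config$n_cells)
    pick <- unique(round(seq(1L, config$n_cells, length.out = k)))
    mv <- cbind(metrics$centroid_x, metrics$centroid_y)[pick, , drop = FALSE]
    fx <- transform_points(config$true_transform, mv) +
      matrix(stats::rnorm(2L * nrow(mv), 0, config$landmark_sigma),
             ncol = 2)
    landmarks <- data.frame(x_moving = mv[, 1], y_moving = mv[, 2],
                            x_fixed = fx[, 1], y_fixed = fx[, 2])
    cen2 <- transform_points(config$true_transform,
                             cbind(metrics$centroid_x, metrics$centroid_y)) +
      matrix(stats::rnorm(2L * config$n_cells, 0, config$centroid_sigma),
             ncol = 2)
    centroids_run2 <- data.frame(cell_id = metrics$cell_id,
                                 x = cen2[, 1], y = cen2[, 2],
                                 stringsAsFactors = FALSE)
  } else {
    landmarks <- data.frame(x_moving = numeric(0), y_moving = numeric(0),
                            x_fixed = numeric(0), y_fixed = numeric(0))
    centroids_run2 <- data.frame(cell_id = character(0), x = numeric(0),
                                 y = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(config = config,
                 panels = panels,
                 masks = geom$masks,
                 cells = geom$cells,
                 metrics = metrics,
                 transcripts_run1 = t1,
                 transcripts_run2 = t2,
                 true_transform = config$true_transform,
                 landmarks = landmarks,
                 centroids_run2 = centroids_run2,
                 counts_v1 = Matrix::Matrix(counts$v1, sparse = TRUE,
                                            dimnames = list(geom$cells$cell_id,
                                                            colnames(counts$v1))),
                 counts_prime = Matrix::Matrix(counts$prime, sparse = TRUE,
                                               dimnames = list(geom$cells$cell_id,
                                                               colnames(counts$prime)))),
            class = "dual_experiment")
}

#' @export
print.dual_experiment <- function(x, ...) {
  cat(sprintf("<dual_experiment: %d cells, %d samples>\n",
              x$config$n_cells, x$config$n_samples))
  cat(sprintf("  run 1 (V1, %d genes): %d transcripts\n",
              x$config$n_genes_v1, nrow(x$transcripts_run1)))
  cat(sprintf("  run 2 (Prime, %d genes): %d transcripts\n",
              x$config$n_genes_prime, nrow(x$transcripts_run2)))
  invisible(x)
}

#' Write / read a dual experiment as a plain-text fixture directory
#'
#' Emits the pipeline's external formats: `transcripts_v1.csv`,
#' `transcripts_prime.csv`, `cell_boundaries.csv` (vertex table),
#' `cells.csv`, `landmarks.csv`, `centroids_run2.csv`, `panel_v1.txt`,
#' `panel_prime.txt`, `secreted_v1.txt`, `secreted_prime.txt` and
#' `true_transform.json`. The tabular files round-trip losslessly.
#'
#' @param experiment a `dual_experiment`.
#' @param dir directory to write into (created if needed).
#' @return `write_fixture` returns `dir` invisibly; `read_fixture` returns a
#'   list of the re-read components.
#' @export
write_fixture <- function(experiment, dir) {
  stopifnot(inherits(experiment, "dual_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcripts(experiment$transcripts_run1,
                    file.path(dir, "transcripts_v1.csv"))
  write_transcripts(experiment$transcripts_run2,
                    file.path(dir, "transcripts_prime.csv"))
  write_masks(experiment$masks, file.path(dir, "cell_boundaries.csv"))
  utils::write.csv(experiment$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  write_landmarks(experiment$landmarks, file.path(dir, "landmarks.csv"))
  utils::write.csv(experiment$centroids_run2,
                   file.path(dir, "centroids_run2.csv"),
                   row.names = FALSE, quote = FALSE)
  write_panel(experiment$panels$v1, file.path(dir, "panel_v1.txt"))
  write_panel(experiment$panels$prime, file.path(dir, "panel_prime.txt"))
  writeLines(experiment$panels$secreted$v1, file.path(dir, "secreted_v1.txt"))
  writeLines(experiment$panels$secreted$prime, file.path(dir, "secreted_prime.txt"))
  write_transform(experiment$true_transform, file.path(dir, "true_transform.json"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  list(transcripts_run1 = read_transcripts(file.path(dir, "transcripts_v1.csv")),
       transcripts_run2 = read_transcripts(file.path(dir, "transcripts_prime.csv")),
       masks = read_masks(file.path(dir, "cell_boundaries.csv")),
       cells = utils::read.csv(file.path(dir, "cells.csv"),
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "character")),
       landmarks = read_landmarks(file.path(dir, "landmarks.csv")),
       centroids_run2 = utils::read.csv(file.path(dir, "centroids_run2.csv"),
                                        stringsAsFactors = FALSE),
       panel_v1 = read_panel(file.path(dir, "panel_v1.txt"), "V1"),
       panel_prime = read_panel(file.path(dir, "panel_prime.txt"), "Prime"),
       secreted_v1 = readLines(file.path(dir, "secreted_v1.txt")),
       secreted_prime = readLines(file.path(dir, "secreted_prime.txt")),
       true_transform = read_transform(file.path(dir, "true_transform.json")))
}
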