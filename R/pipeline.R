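#' Pipeline configuration
#'
#' A single configuration drives the whole simulate - register - assign -
#' merge - stats pipeline. It can be given as a nested list or a YAML file
#' with the same keys; omitted keys fall back to defaults.
#'
#' Keys: `out_dir` (required); `sim` (arguments to [sim_config()]);
#' `register` (`model`, `refine`, `cutoff`); `thresholds` (arguments to
#' [qc_thresholds()]); `stats` (`transform`, `seed`, `n_random`).
#'
#' @param config nested list, or path to a YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir))
    abort_dx("pipeline config needs `out_dir`", "duplexium_config_error")
  sim_args <- config$sim %||% list()
  if (!is.null(sim_args$true_transform) &&
      !inherits(sim_args$true_transform, "affine_transform")) {
    tt <- sim_args$true_transform
    sim_args$true_transform <- similarity_transform(
      rotation_deg = tt$rotation_deg %||% 0, scale = tt$scale %||% 1,
      translation = unlist(tt$translation %||% c(0, 0)))
  }
  reg <- config$register %||% list()
  st <- config$stats %||% list()
  structure(list(
    out_dir = config$out_dir,
    sim = do.call(sim_config, sim_args),
    register = list(model = reg$model %||% "similarity",
                    refine = reg$refine %||% TRUE,
                    cutoff = reg$cutoff %||% 15),
    thresholds = do.call(qc_thresholds, config$thresholds %||% list()),
    stats = list(transform = st$transform %||% "log1p",
                 seed = as.integer(st$seed %||% 17L),
                 n_random = st$n_random)),
    class = "pipeline_config")
}

# derived solo-slide configs: same tissue (expression_seed), fresh cells
solo_configs <- function(sim) {
  solo <- sim
  solo$prime_overlap_attenuation <- 1
  solo$seed <- sim$seed + 1L
  class(solo) <- "sim_config"
  solo
}

stage_simulate <- function(cfg) {
  dir <- file.path(cfg$out_dir, "sim")
  dual <- generate_dual_experiment(cfg$sim)
  write_fixture(dual, file.path(dir, "dual"))
  solo <- generate_dual_experiment(solo_configs(cfg$sim))
  write_fixture(solo, file.path(dir, "solo"))
  message(sprintf("simulate: dual %d + %d transcripts, solo %d + %d transcripts",
                  nrow(dual$transcripts_run1), nrow(dual$transcripts_run2),
                  nrow(solo$transcripts_run1), nrow(solo$transcripts_run2)))
  invisible(NULL)
}

stage_register <- function(cfg) {
  dir <- cfg$out_dir
  landmarks <- read_landmarks(file.path(dir, "sim", "dual", "landmarks.csv"))
  tr <- estimate_transform(landmarks, model = cfg$register$model)
  if (isTRUE(cfg$register$refine)) {
    masks <- read_masks(file.path(dir, "sim", "dual", "cell_boundaries.csv"))
    metrics <- compute_cell_metrics(masks)
    cen2 <- utils::read.csv(file.path(dir, "sim", "dual", "centroids_run2.csv"),
                            stringsAsFactors = FALSE)
    tr <- refine_by_centroids(tr,
                              cbind(metrics$centroid_x, metrics$centroid_y),
                              cbind(cen2$x, cen2$y),
                              cutoff = cfg$register$cutoff)
    tr$rms <- attr(tr, "mean_matched_dist")
  }
  dir.create(file.path(dir, "register"), recursive = TRUE, showWarnings = FALSE)
  write_transform(tr, file.path(dir, "register", "transform.json"))
  message(sprintf("register: %s model, residual RMS %.4g um",
                  tr$model, tr$rms %||% NA))
  invisible(NULL)
}

assign_one_run <- function(transcripts, masks, thresholds) {
  a <- assign_to_masks(transcripts, masks)
  transcripts$cell_id <- a$cell_id
  transcripts$overlaps_nucleus <- a$overlaps_nucleus
  f <- filter_transcripts(transcripts, thresholds)
  list(assigned = transcripts, kept = f$kept, tally = f$tally,
       n_ties = attr(a, "n_ties"))
}

stage_assign <- function(cfg) {
  dir <- cfg$out_dir
  fix <- file.path(dir, "sim", "dual")
  masks <- read_masks(file.path(fix, "cell_boundaries.csv"))
  tr <- read_transform(file.path(dir, "register", "transform.json"))
  t1 <- read_transcripts(file.path(fix, "transcripts_v1.csv"))
  t2 <- read_transcripts(file.path(fix, "transcripts_prime.csv"))
  # run 1 transcripts live in the segmentation's own frame; run 2 transcripts
  # are matched against the masks carried into the second frame
  r1 <- assign_one_run(t1, masks, cfg$thresholds)
  masks2 <- apply_transform(tr, masks)
  r2 <- assign_one_run(t2, masks2, cfg$thresholds)
  adir <- file.path(dir, "assign")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  write_transcripts(r1$assigned, file.path(adir, "transcripts_v1_assigned.csv"))
  write_transcripts(r2$assigned, file.path(adir, "transcripts_prime_assigned.csv"))
  write_transcripts(r1$kept, file.path(adir, "transcripts_v1_kept.csv"))
  write_transcripts(r2$kept, file.path(adir, "transcripts_prime_kept.csv"))
  report <- list(
    v1 = list(total = nrow(r1$assigned), kept = nrow(r1$kept),
              removed = as.list(r1$tally), ties = r1$n_ties),
    prime = list(total = nrow(r2$assigned), kept = nrow(r2$kept),
                 removed = as.list(r2$tally), ties = r2$n_ties))
  jsonlite::write_json(report, file.path(adir, "assignment_report.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("assign: kept %d/%d (V1), %d/%d (Prime)",
                  nrow(r1$kept), nrow(r1$assigned),
                  nrow(r2$kept), nrow(r2$assigned)))
  invisible(NULL)
}

stage_merge <- function(cfg) {
  dir <- cfg$out_dir
  fix <- file.path(dir, "sim", "dual")
  adir <- file.path(dir, "assign")
  masks <- read_masks(file.path(fix, "cell_boundaries.csv"))
  cells <- utils::read.csv(file.path(fix, "cells.csv"), stringsAsFactors = FALSE,
                           colClasses = c("character", "character"))
  metrics <- compute_cell_metrics(masks)
  panel_v1 <- read_panel(file.path(fix, "panel_v1.txt"), "V1")
  panel_prime <- read_panel(file.path(fix, "panel_prime.txt"), "Prime")
  k1 <- read_transcripts(file.path(adir, "transcripts_v1_kept.csv"))
  k2 <- read_transcripts(file.path(adir, "transcripts_prime_kept.csv"))
  dm <- build_matrix(k1, k2, panel_v1, panel_prime, metrics, cells)
  mdir <- file.path(dir, "merge")
  views <- list(combined = view_matrix(dm, "combined"),
                v1 = view_matrix(dm, "v1"),
                prime = view_matrix(dm, "prime"))
  for (nm in names(views))
    write_matrix(views[[nm]], file.path(mdir, nm))
  filt <- lapply(views, filter_cells, thresholds = cfg$thresholds)
  rep_ <- retention_report(filt)
  utils::write.table(rep_$slide, file.path(mdir, "retention_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(rep_$per_sample))
    utils::write.table(rep_$per_sample,
                       file.path(mdir, "retention_per_sample.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- views$combined$metrics
  for (nm in names(views))
    meta[[paste0("pass_", nm)]] <- as.integer(
      meta$cell_id %in% filt[[nm]]$retained)
  write_cell_metadata(meta, file.path(mdir, "cell_metadata.csv"))
  message(sprintf("merge: retention combined %.1f%%, V1 %.1f%%, Prime %.1f%%",
                  filt$combined$summary$percent_retained,
                  filt$v1$summary$percent_retained,
                  filt$prime$summary$percent_retained))
  invisible(NULL)
}

stage_stats <- function(cfg) {
  dir <- cfg$out_dir
  fix_dual <- file.path(dir, "sim", "dual")
  fix_solo <- file.path(dir, "sim", "solo")
  sdir <- file.path(dir, "stats")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  tf <- cfg$stats$transform

  panel_v1 <- read_panel(file.path(fix_dual, "panel_v1.txt"), "V1")
  panel_prime <- read_panel(file.path(fix_dual, "panel_prime.txt"), "Prime")
  overlap <- intersect(panel_v1$genes, panel_prime$genes)

  # dual-slide aggregates from the merged matrix views
  meta <- read_cell_metadata(file.path(dir, "merge", "cell_metadata.csv"))
  load_view <- function(name) {
    counts <- read_matrix(file.path(dir, "merge", name))
    pf <- parse_feature(colnames(counts))
    structure(list(counts = counts,
                   features = data.frame(feature = colnames(counts),
                                         gene = pf$gene, panel = pf$panel,
                                         stringsAsFactors = FALSE),
                   metrics = meta[match(rownames(counts), meta$cell_id), ],
                   view = name),
              class = "cell_gene_matrix")
  }
  view_v1 <- load_view("v1")
  view_prime <- load_view("prime")
  agg_dual_v1 <- aggregate_counts(view_v1)
  agg_dual_prime <- aggregate_counts(view_prime)

  # solo slides: transcript-level aggregates under the same upstream filter
  solo_v1_tx <- filter_transcripts(
    read_transcripts(file.path(fix_solo, "transcripts_v1.csv")),
    cfg$thresholds)$kept
  solo_prime_tx <- filter_transcripts(
    read_transcripts(file.path(fix_solo, "transcripts_prime.csv")),
    cfg$thresholds)$kept
  agg_solo_v1 <- aggregate_transcript_counts(solo_v1_tx, panel_v1)
  agg_solo_prime <- aggregate_transcript_counts(solo_prime_tx, panel_prime)

  # slide-level solo-vs-dual correlations
  cor_rows <- do.call(rbind, lapply(
    list(list("V1", agg_solo_v1, agg_dual_v1),
         list("Prime", agg_solo_prime, agg_dual_prime)),
    function(it) data.frame(
      chemistry = it[[1]],
      r_pearson_log1p = correlate_aggregates(it[[2]], it[[3]],
                                             method = "pearson",
                                             transform = "log1p"),
      r_pearson_raw = correlate_aggregates(it[[2]], it[[3]],
                                           method = "pearson",
                                           transform = "raw"),
      r_spearman = correlate_aggregates(it[[2]], it[[3]],
                                        method = "spearman",
                                        transform = "raw"),
      stringsAsFactors = FALSE)))
  utils::write.table(cor_rows, file.path(sdir, "correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  ps <- rbind(
    cbind(chemistry = "V1",
          per_sample_correlation(agg_solo_v1, agg_dual_v1, transform = tf)),
    cbind(chemistry = "Prime",
          per_sample_correlation(agg_solo_prime, agg_dual_prime, transform = tf)))
  utils::write.table(ps, file.path(sdir, "per_sample_correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # solo-vs-dual z-score sensitivity comparison per chemistry
  zrows <- do.call(rbind, lapply(
    list(list("V1", agg_solo_v1, agg_dual_v1),
         list("Prime", agg_solo_prime, agg_dual_prime)),
    function(it) {
      zs <- zscore_across_genes(it[[2]], transform = tf, run = "solo")
      zd <- zscore_across_genes(it[[3]], transform = tf, run = "dual")
      cmp <- compare_overlap_sensitivity(
        zs, zd, overlap,
        n_random = cfg$stats$n_random %||% length(overlap),
        seed = cfg$stats$seed)
      do.call(rbind, lapply(c("overlap", "random"), function(g) {
        s <- cmp[[g]]
        data.frame(chemistry = it[[1]], group = g, n = s$n,
                   median_dz = s$median_dz, p_value = s$p_value,
                   null_consistent = s$null_consistent,
                   stringsAsFactors = FALSE)
      }))
    }))
  utils::write.table(zrows, file.path(sdir, "zscore_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  rho <- per_gene_cross_chemistry_rho(view_v1, view_prime, overlap)
  utils::write.table(rho, file.path(sdir, "per_gene_rho.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  sec_v1 <- readLines(file.path(fix_dual, "secreted_v1.txt"))
  sec_prime <- readLines(file.path(fix_dual, "secreted_prime.txt"))
  sec <- rbind(cbind(panel = "V1",
                     secretome_diversity(view_v1, sec_v1)),
               cbind(panel = "Prime",
                     secretome_diversity(view_prime, sec_prime)))
  utils::write.table(sec, file.path(sdir, "secretome_per_cell.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("stats: solo-vs-dual r(log1p) V1 %.3f, Prime %.3f",
                  cor_rows$r_pearson_log1p[1], cor_rows$r_pearson_log1p[2]))
  invisible(NULL)
}

#' Run the dual-chemistry pipeline
#'
#' Executes the requested stages in order: `simulate` (dual slide plus a
#' solo companion slide of the same simulated tissue), `register` (landmark
#' fit plus optional centroid refinement), `assign` (point-in-polygon
#' re-assignment against the registered masks plus the upstream transcript
#' filter), `merge` (panel-tagged matrices, cell filter, retention report)
#' and `stats` (solo-vs-dual correlations, z-score sensitivity comparison,
#' per-gene cross-chemistry rho, secretome diversity). Each stage reads only
#' its persisted inputs under `out_dir`, so any stage can be re-run in
#' isolation. A manifest of every artifact with its MD5 content hash is
#' written last; with fixed seeds reruns are byte-identical.
#'
#' @param config a [pipeline_config()], nested list, or YAML path.
#' @param stages character vector of stage names to run (in pipeline order).
#' @return The manifest (invisibly): data.frame with `path`, `md5`, `bytes`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "register", "assign",
                                    "merge", "stats")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  all_stages <- c(simulate = stage_simulate, register = stage_register,
                  assign = stage_assign, merge = stage_merge,
                  stats = stage_stats)
  stages <- match.arg(stages, names(all_stages), several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(all_stages)) {
    if (!nm %in% stages) next
    tryCatch(all_stages[[nm]](config),
             error = function(e) {
               abort_dx(sprintf("stage `%s` failed: %s", nm, conditionMessage(e)),
                        "duplexium_pipeline_error")
             })
  }
  manifest <- write_manifest(config$out_dir)
  invisible(manifest)
}

write_manifest <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  paths <- file.path(out_dir, files)
  manifest <- data.frame(path = files,
                         md5 = unname(tools::md5sum(paths)),
                         bytes = file.size(paths),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  manifest
}
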