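# shared fixtures and independent oracles, all built in code

# a small, fast experiment configuration; override fields as needed
small_config <- function(...) {
  args <- list(n_cells = 60L, n_samples = 4L, n_genes_v1 = 40L,
               n_genes_prime = 120L, n_overlap = 20L, seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# square cell mask (side s at origin offset) as a vertex table
square_mask <- function(cell_id, x0 = 0, y0 = 0, side = 1,
                        nucleus_scale = NULL) {
  ring <- data.frame(cell_id = cell_id, ring = "cell", vertex_index = 1:4,
                     x = x0 + c(0, side, side, 0),
                     y = y0 + c(0, 0, side, side),
                     stringsAsFactors = FALSE)
  if (!is.null(nucleus_scale)) {
    c0 <- side * (1 - nucleus_scale) / 2
    nuc <- data.frame(cell_id = cell_id, ring = "nucleus", vertex_index = 1:4,
                      x = x0 + c0 + c(0, 1, 1, 0) * side * nucleus_scale,
                      y = y0 + c0 + c(0, 0, 1, 1) * side * nucleus_scale,
                      stringsAsFactors = FALSE)
    ring <- rbind(ring, nuc)
  }
  ring
}

# independent shoelace implementation (different summation form than the
# package's)
oracle_shoelace <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# brute-force O(points x polygons) assignment oracle: pracma ray casting per
# polygon, smaller-area-then-id tie-break, nucleus flag from the owning cell
oracle_assign <- function(points, masks) {
  P <- if (is.data.frame(points)) cbind(points$x, points$y) else points
  key <- paste(masks$cell_id, masks$ring)
  rings <- split(masks[order(masks$vertex_index), ], key[order(masks$vertex_index)])
  cells <- Filter(function(r) r$ring[1] == "cell", rings)
  areas <- vapply(cells, function(r) oracle_shoelace(r$x, r$y), 0)
  ids <- vapply(cells, function(r) r$cell_id[1], "")
  ord <- order(areas, ids)
  out_id <- rep("UNASSIGNED", nrow(P))
  out_nuc <- rep(0L, nrow(P))
  taken <- rep(FALSE, nrow(P))
  for (k in ord) {
    r <- cells[[k]]
    inside <- pracma::inpolygon(P[, 1], P[, 2], r$x, r$y, boundary = TRUE)
    new <- inside & !taken
    out_id[new] <- ids[k]
    taken <- taken | inside
  }
  for (cid in unique(out_id[out_id != "UNASSIGNED"])) {
    nk <- which(vapply(rings, function(r)
      r$cell_id[1] == cid && r$ring[1] == "nucleus", TRUE))
    if (!length(nk)) next
    r <- rings[[nk]]
    idx <- which(out_id == cid)
    inn <- pracma::inpolygon(P[idx, 1], P[idx, 2], r$x, r$y, boundary = TRUE)
    out_nuc[idx[inn]] <- 1L
  }
  data.frame(cell_id = out_id, overlaps_nucleus = out_nuc,
             stringsAsFactors = FALSE)
}

# paired solo/dual count syntheses of the same simulated tissue
solo_dual_counts <- function(seed, attenuation = 0.8, n_cells = 120L,
                             n_genes_v1 = 150L, n_genes_prime = 750L,
                             n_overlap = 80L, expression_seed = 7L) {
  dual_cfg <- sim_config(n_cells = n_cells, n_genes_v1 = n_genes_v1,
                         n_genes_prime = n_genes_prime, n_overlap = n_overlap,
                         prime_overlap_attenuation = attenuation,
                         seed = seed, expression_seed = expression_seed)
  solo_cfg <- sim_config(n_cells = n_cells, n_genes_v1 = n_genes_v1,
                         n_genes_prime = n_genes_prime, n_overlap = n_overlap,
                         prime_overlap_attenuation = 1,
                         seed = seed + 500000L, expression_seed = expression_seed)
  list(dual = simulate_panel_counts(dual_cfg),
       solo = simulate_panel_counts(solo_cfg),
       overlap = make_overlap_genes(n_overlap))
}

make_overlap_genes <- function(n) sprintf("OVL%04d", seq_len(n))

# solo-vs-dual overlap sensitivity comparison on the Prime chemistry
prime_sensitivity_cmp <- function(seed, attenuation, subset_seed = seed, ...) {
  sd_ <- solo_dual_counts(seed, attenuation = attenuation, ...)
  zs <- zscore_across_genes(aggregate_counts(sd_$solo$prime), run = "solo")
  zd <- zscore_across_genes(aggregate_counts(sd_$dual$prime), run = "dual")
  compare_overlap_sensitivity(zs, zd, sd_$overlap, seed = subset_seed)
}
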