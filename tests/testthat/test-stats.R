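mk_agg <- function(totals, genes = names(totals), samples = NULL) {
  df <- data.frame(feature = genes, gene = genes, panel = "Prime",
                   total = as.numeric(totals), stringsAsFactors = FALSE)
  structure(list(df = df, per_sample = samples), class = "gene_aggregate")
}

test_that("aggregates are column sums, slide-level and per sample", {
  counts <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(1, 1, 2), x = c(3, 4, 7),
                                 dims = c(2, 2),
                                 dimnames = list(c("c1", "c2"), c("A", "B")))
  agg <- aggregate_counts(counts, sample_id = c("S1", "S2"))
  expect_equal(agg$df$total, c(7, 7))
  expect_equal(agg$per_sample["S1", ], c(A = 3, B = 0))
  expect_equal(agg$per_sample["S2", ], c(A = 4, B = 7))
  zero <- aggregate_counts(Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(2, 2),
    dimnames = list(c("c1", "c2"), c("A", "B"))))
  expect_equal(zero$df$total, c(0, 0))
})

test_that("aggregates from a view equal an independent transcript tally", {
  exp <- generate_dual_experiment(small_config(seed = 12))
  k1 <- filter_transcripts(exp$transcripts_run1)$kept
  agg <- aggregate_transcript_counts(k1, exp$panels$v1)
  tally <- table(factor(k1$gene, levels = exp$panels$v1$genes))
  expect_equal(agg$df$total, as.numeric(tally))
  st <- table(factor(k1$sample_id, levels = sort(unique(k1$sample_id))),
              factor(k1$gene, levels = exp$panels$v1$genes))
  expect_equal(unname(rowSums(agg$per_sample)), unname(rowSums(st)))
})

test_that("aggregate correlation has the stated fixed points", {
  a <- mk_agg(c(G1 = 5, G2 = 9, G3 = 1, G4 = 30))
  expect_equal(correlate_aggregates(a, a), 1.0)
  expect_equal(correlate_aggregates(a, a, method = "spearman"), 1.0)
  rev_ranked <- mk_agg(c(G1 = 30, G2 = 1, G3 = 9, G4 = 0.5))
  # b reverses a's ranks
  b <- mk_agg(stats::setNames(max(a$df$total) + 1 - a$df$total, a$df$gene))
  expect_equal(correlate_aggregates(a, b, method = "spearman"), -1.0)
  expect_error(correlate_aggregates(mk_agg(c(G1 = 1, G2 = 2)),
                                    mk_agg(c(G1 = 1, G2 = 2))),
               class = "duplexium_stats_error")
  flat <- mk_agg(c(G1 = 4, G2 = 4, G3 = 4))
  expect_error(correlate_aggregates(flat, a, genes = c("G1", "G2", "G3")),
               class = "duplexium_stats_error")
})

test_that("solo and dual aggregates of the same tissue correlate highly", {
  rs <- vapply(1:20, function(s) {
    sd_ <- solo_dual_counts(s, attenuation = 1, n_cells = 400L,
                            n_genes_prime = 300L, n_overlap = 40L)
    correlate_aggregates(aggregate_counts(sd_$solo$prime),
                         aggregate_counts(sd_$dual$prime))
  }, 0)
  expect_true(all(rs >= 0.95))
})

test_that("per-sample correlation isolates a perturbed sample", {
  set.seed(51)
  genes <- sprintf("G%02d", 1:40)
  per_sample <- matrix(rpois(3 * 40, exp(rnorm(40, 3, 1))), 3, 40,
                       byrow = TRUE, dimnames = list(c("S1", "S2", "S3"), genes))
  a <- mk_agg(colSums(per_sample), genes, per_sample)
  expect_equal(per_sample_correlation(a, a)$r, rep(1, 3))
  perturbed <- per_sample
  perturbed["S2", ] <- rev(perturbed["S2", ])
  b <- mk_agg(colSums(perturbed), genes, perturbed)
  ps <- per_sample_correlation(a, b)
  expect_equal(ps$r[1], 1)
  expect_equal(ps$r[3], 1)
  expect_lt(ps$r[2], 0.5)
})

test_that("17 synthetic samples yield 17 per-sample correlations", {
  cfg <- small_config(n_cells = 170, n_samples = 17, seed = 15)
  exp <- generate_dual_experiment(cfg)
  k <- filter_transcripts(exp$transcripts_run2)$kept
  agg <- aggregate_transcript_counts(k, exp$panels$prime)
  ps <- per_sample_correlation(agg, agg)
  expect_equal(nrow(ps), 17L)
  expect_equal(ps$r[ps$computed], rep(1, sum(ps$computed)), tolerance = 1e-9)
})

test_that("sparse samples are flagged, not computed", {
  genes <- c("G1", "G2", "G3", "G4")
  m <- matrix(c(5, 2, 3, 1,
                1, 0, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), genes))
  a <- mk_agg(colSums(m), genes, m)
  ps <- per_sample_correlation(a, a)
  expect_true(ps$computed[1])
  expect_false(ps$computed[2])
  expect_true(is.na(ps$r[2]))
})

test_that("z-scores use the sample sd and are affine-invariant", {
  z <- zscore_across_genes(mk_agg(c(G1 = 0, G2 = 10)), transform = "raw")
  expect_equal(z$z, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$z), 1, tolerance = 1e-12)
  expect_error(zscore_across_genes(mk_agg(c(G1 = 4, G2 = 4)), transform = "raw"),
               class = "duplexium_stats_error")
  set.seed(3)
  totals <- rpois(30, 40)
  names(totals) <- sprintf("G%02d", 1:30)
  z1 <- zscore_across_genes(mk_agg(totals), transform = "raw")
  z2 <- zscore_across_genes(mk_agg(3 * totals + 7), transform = "raw")
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("z-score tables are standardized to 1e-9 on synthetic aggregates", {
  counts <- simulate_panel_counts(small_config(seed = 61))
  z <- zscore_across_genes(aggregate_counts(counts$prime))
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z$z), 1, tolerance = 1e-9)
})

test_that("the internal signed-rank test matches the reference implementation", {
  set.seed(71)
  for (k in 1:10) {
    d <- rnorm(40, mean = 0.1 * (k %% 3), sd = 1)
    own <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    expect_equal(own$statistic, unname(ref$statistic))
    expect_equal(own$p_value, ref$p.value, tolerance = 1e-9)
  }
  # ties and zeros
  d <- c(0, 1, 1, -1, 2, 2, -2, 3)
  own <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_equal(own$statistic, unname(ref$statistic))
  expect_equal(own$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("identical z tables give zero median shifts in both groups", {
  counts <- simulate_panel_counts(small_config(seed = 81))
  z <- zscore_across_genes(aggregate_counts(counts$prime))
  cmp <- compare_overlap_sensitivity(z, z, make_overlap_genes(20), seed = 5)
  expect_equal(cmp$overlap$median_dz, 0)
  expect_equal(cmp$random$median_dz, 0)
  expect_true(cmp$overlap$null_consistent)
})

test_that("the random-subset draw is seeded and bounded", {
  counts <- simulate_panel_counts(small_config(seed = 82))
  z <- zscore_across_genes(aggregate_counts(counts$prime))
  c1 <- compare_overlap_sensitivity(z, z, make_overlap_genes(20), seed = 9)
  c2 <- compare_overlap_sensitivity(z, z, make_overlap_genes(20), seed = 9)
  expect_identical(c1$random_genes, c2$random_genes)
  expect_error(compare_overlap_sensitivity(z, z, make_overlap_genes(20),
                                           n_random = 1000, seed = 1),
               class = "duplexium_stats_error")
  expect_error(compare_overlap_sensitivity(z, z, character(0)),
               class = "duplexium_stats_error")
})

test_that("attenuation shifts overlap z-scores but not the control subset", {
  cmp <- prime_sensitivity_cmp(seed = 101, attenuation = 0.8)
  expect_gt(cmp$overlap$median_dz, 0)
  expect_lt(cmp$overlap$p_value, 0.01)
  expect_true(cmp$random$null_consistent)
})

test_that("per-gene cross-chemistry rho has the stated fixed points", {
  set.seed(91)
  n <- 200
  x <- rpois(n, 5)
  counts_v1 <- Matrix::Matrix(cbind(x, rpois(n, 3)), sparse = TRUE,
                              dimnames = list(sprintf("c%03d", 1:n),
                                              c("A-V1", "B-V1")))
  counts_pr <- Matrix::Matrix(cbind(x, rpois(n, 3)), sparse = TRUE,
                              dimnames = list(sprintf("c%03d", 1:n),
                                              c("A-Prime", "B-Prime")))
  mk_view <- function(counts, panel) {
    pf <- parse_feature(colnames(counts))
    structure(list(counts = counts,
                   features = data.frame(feature = colnames(counts),
                                         gene = pf$gene, panel = pf$panel,
                                         stringsAsFactors = FALSE),
                   metrics = data.frame(cell_id = rownames(counts)),
                   view = panel),
              class = "cell_gene_matrix")
  }
  v1 <- mk_view(counts_v1, "v1"); pr <- mk_view(counts_pr, "prime")
  rho <- per_gene_cross_chemistry_rho(v1, pr, c("A", "B"))
  expect_equal(rho$rho[rho$gene == "A"], 1.0)
  expect_lt(abs(rho$rho[rho$gene == "B"]), 0.25)

  # zero-variance gene flagged undefined
  counts_pr2 <- counts_pr
  counts_pr2[, "B-Prime"] <- 1
  rho2 <- per_gene_cross_chemistry_rho(v1, mk_view(counts_pr2, "prime"),
                                       c("A", "B"))
  expect_false(rho2$defined[rho2$gene == "B"])
  expect_true(is.na(rho2$rho[rho2$gene == "B"]))

  # roster mismatch
  pr_sub <- mk_view(counts_pr[1:100, ], "prime")
  expect_error(per_gene_cross_chemistry_rho(v1, pr_sub, "A"),
               class = "duplexium_integrity_error")
})

test_that("rho is near zero for independent genes across 100 seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rpois(1000, 4); y <- rpois(1000, 4)
    abs(stats::cor(x, y, method = "spearman")) < 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cross-chemistry rho rises with Prime sensitivity (shared latent)", {
  mean_rho <- vapply(c(5, 30, 115), function(mc) {
    cfg <- small_config(n_cells = 300, mean_counts_prime = mc,
                        overlap_latent_sd = 0.5, seed = 7)
    counts <- simulate_panel_counts(cfg)
    ov <- make_overlap_genes(cfg$n_overlap)
    rhos <- vapply(ov, function(g)
      suppressWarnings(stats::cor(counts$v1[, g], counts$prime[, g],
                                  method = "spearman")), 0)
    mean(rhos, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_rho) > 0))
  expect_true(all(mean_rho < 1))
})

test_that("secretome diversity counts distinct secreted genes per cell", {
  counts <- Matrix::Matrix(matrix(c(2, 0, 1), 1, 3,
                                  dimnames = list("c1", c("A-V1", "B-V1", "C-V1"))),
                           sparse = TRUE)
  view <- structure(list(counts = counts,
                         features = data.frame(feature = colnames(counts),
                                               gene = c("A", "B", "C"),
                                               panel = "V1"),
                         metrics = data.frame(cell_id = "c1"),
                         view = "v1"),
                    class = "cell_gene_matrix")
  expect_equal(secretome_diversity(view, c("A", "B", "C"))$n_secreted, 2L)
  expect_equal(secretome_diversity(view, c("A", "B", "C"),
                                   min_count = 3)$n_secreted, 0L)
  expect_error(secretome_diversity(view, character(0)),
               class = "duplexium_stats_error")
  expect_error(secretome_diversity(view, "NOT_MEASURED"),
               class = "duplexium_stats_error")
})

test_that("a broader secreted panel dominates per-cell diversity", {
  exp <- generate_dual_experiment(small_config(n_cells = 150, seed = 17))
  k1 <- filter_transcripts(exp$transcripts_run1)$kept
  k2 <- filter_transcripts(exp$transcripts_run2)$kept
  dm <- build_matrix(k1, k2, exp$panels$v1, exp$panels$prime,
                     exp$metrics, exp$cells)
  v1 <- view_matrix(dm, "v1"); pr <- view_matrix(dm, "prime")
  s1 <- secretome_diversity(v1, exp$panels$secreted$v1)
  s2 <- secretome_diversity(pr, exp$panels$secreted$prime)
  expect_gt(mean(s2$n_secreted), mean(s1$n_secreted))
  # bound: per-cell diversity cannot exceed detected genes or the set size
  expect_true(all(s2$n_secreted <= pmin(v1$metrics$n_genes +
                                          pr$metrics$n_genes,
                                        length(exp$panels$secreted$prime))))
})

test_that("cluster concordance has exact fixed points and tracks filtering", {
  ids <- sprintf("c%04d", 1:200)
  la <- stats::setNames(rep(c("T", "B", "Mac", "Epi"), 50), ids)
  cc <- cluster_label_concordance(la, la)
  expect_equal(cc$ari, 1.0)
  expect_true(all(cc$table[row(cc$table) != col(cc$table)] == 0))

  # merging two clusters of A into one in B: one 2 -> 1 confluence
  lb <- la
  lb[lb %in% c("T", "B")] <- "Lymph"
  cc2 <- cluster_label_concordance(la, lb)
  expect_equal(sum(cc2$table["T", ] > 0), 1L)
  expect_equal(sum(cc2$table["B", ] > 0), 1L)
  expect_equal(unname(cc2$table["T", "Lymph"]), 50)
  expect_equal(unname(cc2$table["B", "Lymph"]), 50)

  # cells filtered in one labeling appear in the (filtered) margin
  lc <- la[1:150]
  cc3 <- cluster_label_concordance(la, lc)
  expect_equal(sum(cc3$table[, "(filtered)"]), 50)
  expect_equal(cc3$n_shared, 150L)
  expect_error(cluster_label_concordance(la, stats::setNames("x", "zzz")),
               class = "duplexium_stats_error")
})

test_that("adjusted agreement is near zero for random labelings", {
  skip_if_not_installed("mclust")
  ids <- sprintf("c%05d", 1:10000)
  aris <- vapply(1:50, function(s) {
    set.seed(s)
    la <- stats::setNames(sample(paste0("k", 1:5), 10000, replace = TRUE), ids)
    lb <- stats::setNames(sample(paste0("k", 1:5), 10000, replace = TRUE), ids)
    cc <- cluster_label_concordance(la, lb)
    # cross-check against the reference implementation
    expect_equal(cc$ari, mclust::adjustedRandIndex(la[ids], lb[ids]),
                 tolerance = 1e-12)
    cc$ari
  }, 0)
  expect_lt(max(abs(aris)), 0.02)
})
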