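panel_v1 <- panel_definition("V1", c("EPCAM", "SFTPC", "HLA-A", "AGER"))
panel_prime <- panel_definition("Prime", c("EPCAM", "SFTPC", "MKI67"))

test_that("feature tagging is injective and invertible", {
  expect_equal(tag_features("EPCAM", panel_v1), "EPCAM-V1")
  expect_equal(tag_features("EPCAM", panel_prime), "EPCAM-Prime")
  expect_false(tag_features("SFTPC", panel_v1) ==
                 tag_features("SFTPC", panel_prime))
  expect_error(tag_features("NOPE", panel_v1), class = "duplexium_panel_error")
  # inverse round-trip, including a hyphenated gene symbol
  feats <- tag_features(panel_v1$genes, panel_v1)
  parsed <- parse_feature(feats)
  expect_equal(parsed$gene, panel_v1$genes)
  expect_equal(unique(parsed$panel), "V1")
})

make_tx <- function(genes, cells, ids = NULL) {
  n <- length(genes)
  data.frame(transcript_id = ids %||% sprintf("t%d", seq_len(n)),
             gene = genes, x = rep(0, n), y = rep(0, n), qv = rep(40, n),
             overlaps_nucleus = rep(1L, n), cell_id = cells,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

roster2 <- data.frame(cell_id = c("c1", "c2"), sample_id = c("S01", "S01"),
                      stringsAsFactors = FALSE)
metrics2 <- data.frame(cell_id = c("c1", "c2"), cell_area = c(50, 60),
                       nucleus_area = c(10, 12), centroid_x = 0, centroid_y = 0,
                       stringsAsFactors = FALSE)

test_that("match_cells keeps the full roster and ignores row order", {
  t1 <- make_tx(c("EPCAM", "EPCAM", "SFTPC"), c("c1", "c2", "c1"))
  t2 <- make_tx(character(0), character(0))
  m <- match_cells(t1, t2, roster2)
  expect_equal(m$n_run1, c(2L, 1L))
  expect_equal(m$n_run2, c(0L, 0L))
  m_perm <- match_cells(t1[c(3, 1, 2), ], t2, roster2)
  expect_identical(m, m_perm)
  t_bad <- make_tx("EPCAM", "ghost")
  expect_error(match_cells(t_bad, t2, roster2),
               class = "duplexium_integrity_error")
})

test_that("combined counts are additive over the panel views", {
  t1 <- make_tx(c("EPCAM", "SFTPC", "AGER"), c("c1", "c1", "c1"))
  t2 <- make_tx(c("EPCAM", "MKI67"), c("c1", "c1"), ids = c("p1", "p2"))
  dm <- build_matrix(t1, t2, panel_v1, panel_prime, metrics2, roster2)
  v <- lapply(c(combined = "combined", v1 = "v1", prime = "prime"),
              function(x) view_matrix(dm, x))
  expect_equal(v$combined$metrics$n_counts[1], 5L)
  expect_equal(v$v1$metrics$n_counts[1], 3L)
  expect_equal(v$prime$metrics$n_counts[1], 2L)
  expect_equal(v$combined$metrics$n_counts,
               v$v1$metrics$n_counts + v$prime$metrics$n_counts)
  expect_equal(v$combined$metrics$n_genes[1], 5L)
  # zero-transcript cell still present
  expect_equal(v$combined$metrics$n_counts[2], 0L)
  expect_equal(rownames(v$combined$counts), roster2$cell_id)
})

test_that("empty transcript input yields an all-zero matrix on the roster", {
  empty <- make_tx(character(0), character(0))
  dm <- build_matrix(empty, empty, panel_v1, panel_prime, metrics2, roster2)
  v <- view_matrix(dm, "combined")
  expect_equal(sum(v$counts), 0)
  expect_equal(nrow(v$counts), 2L)
  expect_equal(ncol(v$counts), length(panel_v1$genes) + length(panel_prime$genes))
})

test_that("a transcript from outside its declared panel is an error", {
  t1 <- make_tx("MKI67", "c1")  # Prime-only gene in the V1 stream
  t2 <- make_tx(character(0), character(0))
  expect_error(build_matrix(t1, t2, panel_v1, panel_prime, metrics2, roster2),
               class = "duplexium_panel_error")
})

test_that("matrix column sums equal an independent per-gene tally", {
  exp <- generate_dual_experiment(small_config(seed = 31))
  k1 <- filter_transcripts(exp$transcripts_run1)$kept
  k2 <- filter_transcripts(exp$transcripts_run2)$kept
  dm <- build_matrix(k1, k2, panel_definition("V1", exp$panels$v1$genes),
                     panel_definition("Prime", exp$panels$prime$genes),
                     exp$metrics, exp$cells)
  v1 <- view_matrix(dm, "v1")
  tally <- table(factor(k1$gene, levels = exp$panels$v1$genes))
  expect_equal(as.numeric(Matrix::colSums(v1$counts)), as.numeric(tally))
})

test_that("cell filtering is boundary-inclusive and attributes attrition", {
  mk_view <- function(n_counts, n_genes, cell_area, nucleus_area) {
    counts <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                                   dimnames = list("c1", "G-V1"))
    structure(list(counts = counts,
                   metrics = data.frame(cell_id = "c1", sample_id = "S01",
                                        n_counts = n_counts, n_genes = n_genes,
                                        cell_area = cell_area,
                                        nucleus_area = nucleus_area,
                                        stringsAsFactors = FALSE),
                   features = data.frame(feature = "G-V1", gene = "G",
                                         panel = "V1"),
                   view = "v1"),
              class = "cell_gene_matrix")
  }
  at_boundary <- filter_cells(mk_view(50L, 5L, 5, 3))
  expect_equal(at_boundary$retained, "c1")
  at_top <- filter_cells(mk_view(50L, 5L, 140, 3))
  expect_equal(at_top$retained, "c1")
  low_counts <- filter_cells(mk_view(49L, 5L, 5, 3))
  expect_equal(low_counts$lost, "c1")
  expect_equal(unname(low_counts$attrition["n_counts"]), 1)
  expect_equal(unname(low_counts$attrition["n_genes"]), 0)
  too_big <- filter_cells(mk_view(50L, 5L, 140.5, 3))
  expect_equal(unname(too_big$attrition["cell_area"]), 1)

  bad <- mk_view(50L, 5L, 5, NA_real_)
  expect_error(filter_cells(bad), class = "duplexium_integrity_error")
})

test_that("retention percentages reproduce the reported worked example", {
  combined <- retention_summary(815850, 265161, "Combined")
  v1 <- retention_summary(644069, 436942, "V1")
  prime <- retention_summary(510205, 570806, "Prime")
  expect_equal(round(combined$percent_retained, 1), 75.5)
  expect_equal(round(v1$percent_retained, 1), 59.6)
  expect_equal(round(prime$percent_retained, 1), 47.2)
  expect_equal(combined$total, 1081011)
  expect_equal(v1$total, 1081011)
  expect_equal(prime$total, 1081011)
})

test_that("combined retention dominates the single panels on synthetic data", {
  exp <- generate_dual_experiment(small_config(
    n_cells = 150, mean_counts_v1 = 60, mean_counts_prime = 50, seed = 41))
  k1 <- filter_transcripts(exp$transcripts_run1)$kept
  k2 <- filter_transcripts(exp$transcripts_run2)$kept
  dm <- build_matrix(k1, k2, panel_definition("V1", exp$panels$v1$genes),
                     panel_definition("Prime", exp$panels$prime$genes),
                     exp$metrics, exp$cells)
  filt <- lapply(c(combined = "combined", v1 = "v1", prime = "prime"),
                 function(x) filter_cells(view_matrix(dm, x)))
  rep_ <- retention_report(filt)
  expect_equal(rep_$slide$retained + rep_$slide$lost,
               rep(150, 3))
  expect_gte(filt$combined$summary$retained,
             max(filt$v1$summary$retained, filt$prime$summary$retained))
  # exact set-level dominance: every cell retained in a panel view is
  # retained in the combined view
  expect_true(all(filt$v1$retained %in% filt$combined$retained))
  expect_true(all(filt$prime$retained %in% filt$combined$retained))
  # idempotence on the retained set
  sub <- view_matrix(dm, "combined")
  keep <- sub$metrics$cell_id %in% filt$combined$retained
  sub$counts <- sub$counts[keep, , drop = FALSE]
  sub$metrics <- sub$metrics[keep, , drop = FALSE]
  expect_equal(length(filter_cells(sub)$retained), sum(keep))
})

test_that("retention report rejects mismatched rosters and handles edge cases", {
  mk_res <- function(retained, lost, panel) {
    list(retained = retained, lost = lost,
         summary = retention_summary(length(retained), length(lost), panel),
         per_sample = NULL)
  }
  ok <- list(a = mk_res(c("c1", "c2"), character(0), "V1"),
             b = mk_res("c1", "c2", "Prime"))
  rep_ <- retention_report(ok)
  expect_equal(rep_$slide$percent_retained, c(100, 50))
  bad <- list(a = mk_res(c("c1", "c2"), character(0), "V1"),
              b = mk_res("c1", "c3", "Prime"))
  expect_error(retention_report(bad), class = "duplexium_integrity_error")
  single <- retention_report(list(a = mk_res("c1", character(0), "V1")))
  expect_true(single$slide$percent_retained %in% c(0, 100))
})
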