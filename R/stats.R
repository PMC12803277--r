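#' Aggregate expression across all cells per gene
#'
#' Pseudobulk totals: each gene's expression is summed over all cells of the
#' slide, and additionally within each sample (TMA core) region.
#'
#' @param x a `cell_gene_matrix` view, or a plain cells x genes (count)
#'   matrix.
#' @param sample_id optional per-cell sample labels when `x` is a plain
#'   matrix.
#' @return A `gene_aggregate`: list with `df` (feature, gene, panel, total)
#'   and `per_sample` (samples x genes totals matrix, or `NULL`).
#' @export
aggregate_counts <- function(x, sample_id = NULL) {
  if (inherits(x, "cell_gene_matrix")) {
    counts <- x$counts
    df <- data.frame(feature = x$features$feature, gene = x$features$gene,
                     panel = x$features$panel, stringsAsFactors = FALSE)
    sample_id <- x$metrics$sample_id
  } else {
    counts <- x
    df <- data.frame(feature = colnames(x), gene = colnames(x),
                     panel = NA_character_, stringsAsFactors = FALSE)
  }
  df$total <- as.numeric(Matrix::colSums(counts))
  per_sample <- NULL
  if (!is.null(sample_id) && !all(is.na(sample_id))) {
    groups <- sort(unique(sample_id))
    per_sample <- do.call(rbind, lapply(groups, function(s) {
      Matrix::colSums(counts[sample_id == s, , drop = FALSE])
    }))
    rownames(per_sample) <- groups
    colnames(per_sample) <- df$gene
  }
  structure(list(df = df, per_sample = per_sample), class = "gene_aggregate")
}

#' Aggregate kept transcripts per gene without building a matrix
#'
#' Transcript-level pseudobulk for a single run: tallies kept transcripts by
#' gene over the run's full panel (genes without any transcript get total 0),
#' slide-level and per sample.
#'
#' @param transcripts kept transcript data.frame (with `gene` and optionally
#'   `sample_id` columns).
#' @param panel a [panel_definition()]; tallies are reported over all its
#'   genes.
#' @return A `gene_aggregate` (see [aggregate_counts()]).
#' @export
aggregate_transcript_counts <- function(transcripts, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  bad <- setdiff(unique(transcripts$gene), panel$genes)
  if (length(bad))
    abort_dx(sprintf("transcript gene(s) absent from panel %s: %s", panel$name,
                     paste(utils::head(bad, 5), collapse = ", ")),
             "duplexium_panel_error")
  g <- factor(transcripts$gene, levels = panel$genes)
  df <- data.frame(feature = tag_features(panel$genes, panel),
                   gene = panel$genes, panel = panel$name,
                   total = as.numeric(table(g)), stringsAsFactors = FALSE)
  per_sample <- NULL
  if ("sample_id" %in% names(transcripts) &&
      any(!is.na(transcripts$sample_id))) {
    tab <- table(transcripts$sample_id, g)
    per_sample <- matrix(as.numeric(tab), nrow = nrow(tab),
                         dimnames = list(rownames(tab), panel$genes))
  }
  structure(list(df = df, per_sample = per_sample), class = "gene_aggregate")
}

agg_totals <- function(a) {
  stopifnot(inherits(a, "gene_aggregate"))
  stats::setNames(a$df$total, a$df$gene)
}

apply_count_transform <- function(x, transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  if (transform == "log1p") log1p(x) else x
}

#' Correlate two runs' per-gene aggregate expression
#'
#' The slide-level concordance statistic between two runs: totals of the
#' shared genes are optionally `log1p`-transformed and correlated. Raw-scale
#' Pearson is dominated by a handful of highly expressed genes, so the
#' default transform is `log1p`; both are exposed.
#'
#' @param a,b `gene_aggregate` objects.
#' @param genes gene set to correlate over; default all shared genes.
#' @param method `"pearson"` or `"spearman"`.
#' @param transform `"log1p"` (default) or `"raw"`.
#' @return The correlation coefficient (length-1 numeric).
#' @export
correlate_aggregates <- function(a, b, genes = NULL,
                                 method = c("pearson", "spearman"),
                                 transform = c("log1p", "raw")) {
  method <- match.arg(method)
  ta <- agg_totals(a); tb <- agg_totals(b)
  genes <- genes %||% intersect(names(ta), names(tb))
  miss <- setdiff(genes, intersect(names(ta), names(tb)))
  if (length(miss))
    abort_dx(sprintf("gene(s) absent from an aggregate: %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "duplexium_stats_error")
  if (length(genes) < 3L)
    abort_dx("need at least 3 shared genes", "duplexium_stats_error")
  x <- apply_count_transform(ta[genes], transform)
  y <- apply_count_transform(tb[genes], transform)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_dx("correlation undefined: zero variance across genes",
             "duplexium_stats_error")
  stats::cor(x, y, method = method)
}

#' Per-sample solo-vs-dual correlation
#'
#' Applies [correlate_aggregates()] within each sample region shared by the
#' two aggregates. Samples with fewer than 3 expressed genes (nonzero in
#' either run) are flagged and left uncomputed.
#'
#' @inheritParams correlate_aggregates
#' @return data.frame with `sample_id`, `r` (NA when not computed),
#'   `n_genes` used, and `computed` flag.
#' @export
per_sample_correlation <- function(a, b, genes = NULL,
                                   method = c("pearson", "spearman"),
                                   transform = c("log1p", "raw")) {
  method <- match.arg(method); transform <- match.arg(transform)
  if (is.null(a$per_sample) || is.null(b$per_sample))
    abort_dx("aggregates lack per-sample totals", "duplexium_stats_error")
  genes <- genes %||% intersect(colnames(a$per_sample), colnames(b$per_sample))
  samples <- intersect(rownames(a$per_sample), rownames(b$per_sample))
  out <- data.frame(sample_id = samples, r = NA_real_,
                    n_genes = NA_integer_, computed = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(samples)) {
    x <- a$per_sample[samples[k], genes]
    y <- b$per_sample[samples[k], genes]
    expressed <- x > 0 | y > 0
    out$n_genes[k] <- sum(expressed)
    if (sum(expressed) < 3L) next
    xt <- apply_count_transform(x[expressed], transform)
    yt <- apply_count_transform(y[expressed], transform)
    if (stats::sd(xt) == 0 || stats::sd(yt) == 0) next
    out$r[k] <- stats::cor(xt, yt, method = method)
    out$computed[k] <- TRUE
  }
  out
}

#' Z-score expression across genes within one run
#'
#' Standardises each gene's slide-level aggregate within a run:
#' `z_g = (x_g - mean(x)) / sd(x)` over the genes of the run's panel, where
#' `x_g` is the (by default `log1p`-transformed) total. Sample standard
#' deviation (n - 1 denominator) is used. The resulting table has mean 0 and
#' sd 1 by construction, which makes runs with different overall sensitivity
#' comparable gene-by-gene.
#'
#' @param aggregates a `gene_aggregate` from [aggregate_counts()].
#' @param transform `"log1p"` (default) or `"raw"`.
#' @param run label stored with the table.
#' @return A `zscore_table`: data.frame with `gene` and `z`, plus `run` and
#'   `transform` attributes.
#' @export
zscore_across_genes <- function(aggregates, transform = c("log1p", "raw"),
                                run = "run") {
  transform <- match.arg(transform)
  x <- apply_count_transform(agg_totals(aggregates), transform)
  if (length(x) < 2L)
    abort_dx("need at least 2 genes to z-score", "duplexium_stats_error")
  s <- stats::sd(x)
  if (s == 0)
    abort_dx("z-scores undefined: all gene totals equal", "duplexium_stats_error")
  out <- data.frame(gene = names(x), z = (x - mean(x)) / s,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "run") <- run
  attr(out, "transform") <- transform
  class(out) <- c("zscore_table", "data.frame")
  out
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired rank test used for the solo-vs-dual z-score shifts: zeros are
#' dropped, absolute differences are ranked with average ranks for ties, and
#' the sum of positive ranks is compared to its null mean with a tie-corrected
#' variance and continuity correction.
#'
#' @param d numeric vector of paired differences.
#' @return list with `statistic` (V, sum of positive ranks), `n_used`
#'   (nonzero differences), `z` and two-sided `p_value`.
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, n_used = 0L, z = NA_real_,
                p_value = NA_real_))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0)
    return(list(statistic = v, n_used = n, z = 0, p_value = 1))
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
  list(statistic = v, n_used = n, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Compare solo-vs-dual sensitivity for overlapping genes
#'
#' Tests whether genes targeted by both panels lose sensitivity in the dual
#' run. For each gene present in both z-score tables the paired shift
#' `dz = z_solo - z_dual` is formed, separately for (i) the overlap gene set
#' and (ii) a seeded random subset of `n_random` non-overlapping genes (a
#' negative control: competitive binding should shift the overlap group only).
#' Each group gets its median shift and an internal Wilcoxon signed-rank
#' test; a group is called null-consistent when its signed-rank p-value is at
#' least `null_alpha`.
#'
#' @param z_solo,z_dual `zscore_table`s from the same panel's solo and dual
#'   runs.
#' @param overlap_genes character vector of genes targeted by both panels.
#' @param n_random size of the random non-overlap subset (default: the
#'   overlap set size).
#' @param seed integer seed for the subset draw (sampled without
#'   replacement).
#' @param null_alpha signed-rank p-value threshold below which a group is no
#'   longer called null-consistent.
#' @return list with `overlap` and `random` group summaries (`n`,
#'   `median_dz`, `statistic`, `p_value`, `null_consistent`) and
#'   `random_genes`.
#' @export
compare_overlap_sensitivity <- function(z_solo, z_dual, overlap_genes,
                                        n_random = length(overlap_genes),
                                        seed = 1L, null_alpha = 0.01) {
  if (length(overlap_genes) == 0L)
    abort_dx("overlap gene set is empty", "duplexium_stats_error")
  shared <- intersect(z_solo$gene, z_dual$gene)
  ov <- intersect(overlap_genes, shared)
  if (length(ov) == 0L)
    abort_dx("no overlap genes present in both z-score tables",
             "duplexium_stats_error")
  non_ov <- setdiff(shared, overlap_genes)
  if (n_random > length(non_ov))
    abort_dx(sprintf("n_random = %d exceeds the %d available non-overlapping genes",
                     n_random, length(non_ov)),
             "duplexium_stats_error")
  rnd <- with_seed(seed, sample(non_ov, n_random))
  dz <- function(genes) {
    z1 <- z_solo$z[match(genes, z_solo$gene)]
    z2 <- z_dual$z[match(genes, z_dual$gene)]
    z1 - z2
  }
  group_summary <- function(genes) {
    d <- dz(genes)
    w <- wilcoxon_signed_rank(d)
    list(n = length(d), median_dz = stats::median(d),
         statistic = w$statistic, p_value = w$p_value,
         null_consistent = is.na(w$p_value) || w$p_value >= null_alpha)
  }
  list(overlap = group_summary(ov),
       random = group_summary(rnd),
       random_genes = sort(rnd))
}

#' Per-gene cross-chemistry rank correlation
#'
#' For every gene targeted by both panels, the Spearman rank correlation
#' across cells between its V1-tagged and Prime-tagged counts in the dual
#' slide. Genes with zero variance in either view are flagged undefined
#' rather than computed.
#'
#' @param view_v1,view_prime `cell_gene_matrix` views of the same dual
#'   matrix; rosters must be identical.
#' @param shared_genes gene symbols to compare; default: genes present in
#'   both views.
#' @return data.frame with `gene`, `rho` (NA when undefined) and `defined`.
#' @export
per_gene_cross_chemistry_rho <- function(view_v1, view_prime,
                                         shared_genes = NULL) {
  if (!identical(rownames(view_v1$counts), rownames(view_prime$counts)))
    abort_dx("views do not share a cell roster", "duplexium_integrity_error")
  shared_genes <- shared_genes %||%
    intersect(view_v1$features$gene, view_prime$features$gene)
  j1 <- match(shared_genes, view_v1$features$gene)
  j2 <- match(shared_genes, view_prime$features$gene)
  if (anyNA(j1) || anyNA(j2))
    abort_dx("shared_genes contains genes absent from a view",
             "duplexium_stats_error")
  out <- data.frame(gene = shared_genes, rho = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(shared_genes)) {
    x <- as.numeric(view_v1$counts[, j1[k]])
    y <- as.numeric(view_prime$counts[, j2[k]])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out$rho[k] <- stats::cor(x, y, method = "spearman")
    out$defined[k] <- TRUE
  }
  out
}

#' Per-cell secreted-gene diversity
#'
#' Counts, for every cell, the number of distinct secreted genes detected at
#' `min_count` or more transcripts in the given view. A broad panel detects a
#' wider secreted repertoire per cell than a small panel even at lower
#' per-gene sensitivity.
#'
#' @param view a `cell_gene_matrix`.
#' @param secreted_genes character vector of secreted gene symbols.
#' @param min_count detection threshold per gene (default 1).
#' @return data.frame with `cell_id` and `n_secreted`.
#' @export
secretome_diversity <- function(view, secreted_genes, min_count = 1L) {
  if (length(secreted_genes) == 0L)
    abort_dx("secreted gene set is empty", "duplexium_stats_error")
  keep <- view$features$gene %in% secreted_genes
  if (!any(keep))
    abort_dx("no secreted gene is measured in this view", "duplexium_stats_error")
  sub <- view$counts[, keep, drop = FALSE]
  data.frame(cell_id = rownames(sub),
             n_secreted = as.integer(Matrix::rowSums(sub >= min_count)),
             stringsAsFactors = FALSE)
}

#' Cluster-label concordance across two labelings
#'
#' Cross-tabulates two cluster labelings of (largely) the same cells and
#' reports a chance-adjusted agreement score. Cells present in only one
#' labeling (e.g. filtered out under that view's QC) are tracked in the
#' contingency table under `"(filtered)"`; the adjusted Rand index is
#' computed on the shared cells only, from the contingency table.
#'
#' @param labels_a,labels_b named vectors (names are cell ids, values are
#'   cluster labels).
#' @return list with `table` (full cross-tabulation including filtered
#'   margins), `ari` (adjusted Rand index on shared cells) and `n_shared`.
#' @export
cluster_label_concordance <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    abort_dx("labelings must be named by cell id", "duplexium_stats_error")
  shared <- intersect(names(labels_a), names(labels_b))
  if (length(shared) == 0L)
    abort_dx("labelings share no cells", "duplexium_stats_error")
  all_ids <- union(names(labels_a), names(labels_b))
  la <- ifelse(all_ids %in% names(labels_a),
               as.character(labels_a[all_ids]), "(filtered)")
  lb <- ifelse(all_ids %in% names(labels_b),
               as.character(labels_b[all_ids]), "(filtered)")
  full <- table(a = la, b = lb)
  ct <- table(as.character(labels_a[shared]), as.character(labels_b[shared]))
  list(table = full, ari = adjusted_rand_from_table(ct),
       n_shared = length(shared))
}

# adjusted Rand index from a contingency table
adjusted_rand_from_table <- function(ct) {
  n <- sum(ct)
  if (n < 2) return(NA_real_)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(ct))
  sa <- sum(comb2(rowSums(ct)))
  sb <- sum(comb2(colSums(ct)))
  expected <- sa * sb / comb2(n)
  denom <- (sa + sb) / 2 - expected
  if (abs(denom) < .Machine$double.eps) return(1)
  (sij - expected) / denom
}
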