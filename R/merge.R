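#' Panel-tagged feature names
#'
#' The two panels share target genes, so features of the combined matrix are
#' made unique by appending the panel name: gene `SFTPC` measured by the V1
#' chemistry becomes feature `SFTPC-V1`. `tag_features` is injective over
#' (gene, panel); `parse_feature` is its inverse.
#'
#' @param genes character vector of gene symbols, each a member of `panel`.
#' @param panel a [panel_definition()].
#' @param features character vector of tagged feature names.
#' @return `tag_features`: character vector of `"<gene>-<panel>"` names;
#'   `parse_feature`: data.frame with `gene` and `panel` columns.
#' @export
tag_features <- function(genes, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  bad <- setdiff(genes, panel$genes)
  if (length(bad))
    abort_dx(sprintf("gene(s) not in panel %s: %s", panel$name,
                     paste(utils::head(bad, 5), collapse = ", ")),
             "duplexium_panel_error")
  paste0(genes, "-", panel$name)
}

#' @rdname tag_features
#' @export
parse_feature <- function(features) {
  pos <- regexpr("-[^-]*$", features)
  if (any(pos < 0))
    abort_dx("feature name without a panel tag", "duplexium_panel_error")
  data.frame(gene = substr(features, 1, pos - 1),
             panel = substr(features, pos + 1, nchar(features)),
             stringsAsFactors = FALSE)
}

#' Match cells across the two runs of a dual slide
#'
#' Both runs' transcripts are assigned against the same (transformed)
#' segmentation, so cells are matched by the shared `cell_id`. Every cell of
#' the roster appears exactly once, including cells with zero transcripts in
#' one or both runs; ordering is the roster's (stable and deterministic, so
#' permuting the transcript rows does not change the result).
#'
#' @param run1_transcripts,run2_transcripts transcript data.frames whose
#'   `cell_id` columns reference the shared segmentation (unassigned rows are
#'   ignored).
#' @param cells roster data.frame with `cell_id` (and optionally
#'   `sample_id`).
#' @return data.frame with `cell_id`, optional `sample_id`, `n_run1`,
#'   `n_run2` transcript counts per cell.
#' @export
match_cells <- function(run1_transcripts, run2_transcripts, cells) {
  roster <- cells$cell_id
  count_in <- function(tx, label) {
    ids <- tx$cell_id[tx$cell_id != "UNASSIGNED"]
    unknown <- setdiff(ids, roster)
    if (length(unknown))
      abort_dx(sprintf("%s references cell id(s) absent from the roster: %s",
                       label, paste(utils::head(unknown, 5), collapse = ", ")),
               "duplexium_integrity_error")
    tab <- table(factor(ids, levels = roster))
    as.integer(tab)
  }
  out <- data.frame(cell_id = roster, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(cells)) out$sample_id <- cells$sample_id
  out$n_run1 <- count_in(run1_transcripts, "run 1")
  out$n_run2 <- count_in(run2_transcripts, "run 2")
  out
}

# counts matrix (cells x tagged features) from kept transcripts of one run
tally_counts <- function(transcripts, panel, roster) {
  bad <- setdiff(unique(transcripts$gene), panel$genes)
  if (length(bad))
    abort_dx(sprintf("transcript gene(s) absent from panel %s: %s", panel$name,
                     paste(utils::head(bad, 5), collapse = ", ")),
             "duplexium_panel_error")
  feats <- tag_features(panel$genes, panel)
  i <- match(transcripts$cell_id, roster)
  if (anyNA(i))
    abort_dx("transcript references a cell id absent from the roster",
             "duplexium_integrity_error")
  j <- match(transcripts$gene, panel$genes)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(roster), length(feats)),
                       dimnames = list(roster, feats))
}

#' Build the panel-tagged dual cell-by-gene matrix
#'
#' Tallies the (filtered, assigned) transcripts of each run into a cells x
#' features count matrix with panel-tagged feature names and concatenates the
#' two panels' columns. All roster cells appear as rows even with zero
#' transcripts, so the V1-only, Prime-only and Combined views share one cell
#' roster.
#'
#' @param transcripts_v1,transcripts_prime kept transcript data.frames of
#'   the two runs (only rows with a cell assignment are tallied).
#' @param panel_v1,panel_prime [panel_definition()]s; every transcript gene
#'   must belong to its run's panel.
#' @param metrics per-cell geometry from [compute_cell_metrics()].
#' @param cells roster data.frame (`cell_id`, `sample_id`).
#' @return A `dual_matrix` object (counts, feature table, per-cell
#'   metadata). Use [view_matrix()] to extract a panel view.
#' @export
build_matrix <- function(transcripts_v1, transcripts_prime,
                         panel_v1, panel_prime, metrics, cells) {
  roster <- cells$cell_id
  if (anyDuplicated(roster))
    abort_dx("duplicate cell ids in roster", "duplexium_integrity_error")
  miss <- setdiff(roster, metrics$cell_id)
  if (length(miss))
    abort_dx(sprintf("missing geometry metrics for cell(s): %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "duplexium_integrity_error")
  keep_assigned <- function(tx) tx[tx$cell_id != "UNASSIGNED", , drop = FALSE]
  m_v1 <- tally_counts(keep_assigned(transcripts_v1), panel_v1, roster)
  m_pr <- tally_counts(keep_assigned(transcripts_prime), panel_prime, roster)
  counts <- cbind(m_v1, m_pr)
  features <- data.frame(feature = colnames(counts),
                         gene = c(panel_v1$genes, panel_prime$genes),
                         panel = rep(c(panel_v1$name, panel_prime$name),
                                     c(length(panel_v1$genes),
                                       length(panel_prime$genes))),
                         stringsAsFactors = FALSE)
  meta <- metrics[match(roster, metrics$cell_id),
                  c("cell_id", "cell_area", "nucleus_area")]
  meta$sample_id <- if ("sample_id" %in% names(cells)) cells$sample_id
  else NA_character_
  rownames(meta) <- NULL
  structure(list(counts = counts, features = features, metadata = meta,
                 panel_names = c(v1 = panel_v1$name, prime = panel_prime$name)),
            class = "dual_matrix")
}

#' @export
print.dual_matrix <- function(x, ...) {
  cat(sprintf("<dual_matrix: %d cells x %d features (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$features$panel), collapse = " + ")))
  invisible(x)
}

#' Extract a panel view of a dual matrix
#'
#' A view restricts the columns to one panel's features (or keeps all for
#' `"combined"`) and computes the per-cell QC metrics on those columns only:
#' `n_counts` (row sum) and `n_genes` (nonzero entries per row). Combined
#' `n_counts` is therefore the sum of the per-panel `n_counts` of the same
#' cell.
#'
#' @param dual a `dual_matrix` from [build_matrix()].
#' @param view `"v1"`, `"prime"` or `"combined"`.
#' @return A `cell_gene_matrix`: list with `counts` (cells x features
#'   dgCMatrix), `metrics` (per-cell data.frame with `n_counts`, `n_genes`,
#'   `cell_area`, `nucleus_area`, `sample_id`), `features` and `view`.
#' @export
view_matrix <- function(dual, view = c("combined", "v1", "prime")) {
  stopifnot(inherits(dual, "dual_matrix"))
  view <- match.arg(view)
  keep <- switch(view,
                 combined = rep(TRUE, nrow(dual$features)),
                 v1 = dual$features$panel == dual$panel_names[["v1"]],
                 prime = dual$features$panel == dual$panel_names[["prime"]])
  counts <- dual$counts[, keep, drop = FALSE]
  metrics <- dual$metadata
  metrics$n_counts <- as.integer(Matrix::rowSums(counts))
  metrics$n_genes <- as.integer(Matrix::rowSums(counts > 0))
  structure(list(counts = counts, metrics = metrics,
                 features = dual$features[keep, , drop = FALSE],
                 view = view),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("<cell_gene_matrix [%s]: %d cells x %d features>\n",
              x$view, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Retention arithmetic for a filtered view
#'
#' @param retained,lost cell counts.
#' @param panel label for the view (`"V1"`, `"Prime"`, `"Combined"`, ...).
#' @return A `retention_summary`: list with `panel`, `total`, `retained`,
#'   `lost` and `percent_retained = 100 * retained / total`.
#' @export
retention_summary <- function(retained, lost, panel = "Combined") {
  retained <- as.numeric(retained); lost <- as.numeric(lost)
  if (retained < 0 || lost < 0)
    abort_dx("counts must be nonnegative", "duplexium_config_error")
  total <- retained + lost
  structure(list(panel = panel, total = total, retained = retained,
                 lost = lost,
                 percent_retained = if (total > 0) 100 * retained / total
                 else NA_real_),
            class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat(sprintf("<%s: %s/%s cells retained (%.1f%%)>\n", x$panel,
              format(x$retained, big.mark = ","),
              format(x$total, big.mark = ","), x$percent_retained))
  invisible(x)
}

#' Cell-level quality filter with retention accounting
#'
#' A cell is retained iff all four conditions hold on the given view:
#' `n_counts >= min_counts`, `n_genes >= min_genes`, `cell_area` within
#' `cell_area_range` (inclusive) and `nucleus_area >= nucleus_area_min`.
#' The per-threshold attrition table reports how many cells fail each
#' condition (non-exclusive), identifying which filter dominates retention.
#'
#' @param view a `cell_gene_matrix` from [view_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `retained` / `lost` cell-id vectors, `summary`
#'   (a [retention_summary()]), `attrition` (per-threshold failure counts)
#'   and `per_sample` retention breakdown.
#' @export
filter_cells <- function(view, thresholds = qc_thresholds()) {
  stopifnot(inherits(view, "cell_gene_matrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- view$metrics
  need <- c("n_counts", "n_genes", "cell_area", "nucleus_area")
  for (col in need) {
    if (!col %in% names(m) || anyNA(m[[col]]))
      abort_dx(sprintf("missing metric `%s`%s", col,
                       if (col %in% names(m))
                         sprintf(" for cell(s) %s",
                                 paste(utils::head(m$cell_id[is.na(m[[col]])], 5),
                                       collapse = ", "))
                       else ""),
               "duplexium_integrity_error")
  }
  fail <- cbind(n_counts = m$n_counts < thresholds$min_counts,
                n_genes = m$n_genes < thresholds$min_genes,
                cell_area = m$cell_area < thresholds$cell_area_range[1] |
                  m$cell_area > thresholds$cell_area_range[2],
                nucleus_area = m$nucleus_area < thresholds$nucleus_area_min)
  pass <- !apply(fail, 1L, any)
  label <- c(v1 = "V1", prime = "Prime", combined = "Combined")[view$view]
  per_sample <- NULL
  if ("sample_id" %in% names(m) && !all(is.na(m$sample_id))) {
    agg <- stats::aggregate(cbind(retained = pass, total = rep(1L, length(pass))),
                            by = list(sample_id = m$sample_id), FUN = sum)
    agg$lost <- agg$total - agg$retained
    agg$percent_retained <- 100 * agg$retained / agg$total
    per_sample <- agg[order(agg$sample_id), ]
    rownames(per_sample) <- NULL
  }
  list(retained = m$cell_id[pass],
       lost = m$cell_id[!pass],
       summary = retention_summary(sum(pass), sum(!pass), panel = label),
       attrition = colSums(fail),
       per_sample = per_sample)
}

#' Cross-view retention report
#'
#' Combines the [filter_cells()] results of the V1-only, Prime-only and
#' Combined views (which must share one cell roster) into a single table,
#' slide-level and per sample. Because the combined view's `n_counts` and
#' `n_genes` dominate each panel view's values while the area filters are
#' shared, combined retention is at least the maximum single-panel retention;
#' the report errors if the rosters disagree.
#'
#' @param results named list of [filter_cells()] results (e.g.
#'   `list(combined = ..., v1 = ..., prime = ...)`).
#' @return list with `slide` (one row per view: total/retained/lost/percent)
#'   and `per_sample` (long table keyed by view and sample).
#' @export
retention_report <- function(results) {
  rosters <- lapply(results, function(r) sort(c(r$retained, r$lost)))
  for (k in seq_along(rosters)[-1]) {
    if (!identical(rosters[[1]], rosters[[k]]))
      abort_dx("views were filtered on different cell rosters",
               "duplexium_integrity_error")
  }
  slide <- do.call(rbind, lapply(results, function(r) {
    s <- r$summary
    data.frame(panel = s$panel, total = s$total, retained = s$retained,
               lost = s$lost, percent_retained = s$percent_retained,
               stringsAsFactors = FALSE)
  }))
  rownames(slide) <- NULL
  per_sample <- do.call(rbind, lapply(names(results), function(nm) {
    ps <- results[[nm]]$per_sample
    if (is.null(ps)) return(NULL)
    ps$panel <- results[[nm]]$summary$panel
    ps
  }))
  list(slide = slide, per_sample = per_sample)
}
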