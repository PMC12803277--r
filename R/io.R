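#' Read and write decoded-transcript tables
#'
#' Transcript tables are UTF-8 CSV with a header and one row per decoded
#' transcript. Mandatory columns: `transcript_id`, `gene`, `x`, `y`
#' (micrometers), `qv` (Phred-like decoding quality), `overlaps_nucleus`
#' (0/1) and `cell_id` (with the literal sentinel `"UNASSIGNED"` for
#' transcripts outside every cell). Extra columns (e.g. `sample_id`) are
#' preserved untouched.
#'
#' @param path CSV file path.
#' @param transcripts data.frame of transcript records.
#' @return `read_transcripts` returns the validated data.frame;
#'   `write_transcripts` returns `path` invisibly.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "x", "y", "qv", "overlaps_nucleus", "cell_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_dx(sprintf("transcript table %s missing mandatory column(s): %s",
                     path, paste(miss, collapse = ", ")),
             "duplexium_schema_error")
  df$cell_id <- as.character(df$cell_id)
  df$gene <- as.character(df$gene)
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      abort_dx("transcript coordinates must be finite", "duplexium_schema_error")
    if (any(df$qv < 0)) abort_dx("qv must be >= 0", "duplexium_schema_error")
    if (any(!nzchar(df$gene))) abort_dx("gene symbols must be non-empty",
                                        "duplexium_schema_error")
  }
  df
}

#' @rdname read_transcripts
#' @export
write_transcripts <- function(transcripts, path) {
  utils::write.csv(transcripts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write segmentation-mask vertex tables
#'
#' Masks are stored as a vertex table: columns `cell_id`, `ring` (`"cell"` or
#' `"nucleus"`), `vertex_index` (order around the ring), `x`, `y`
#' (micrometers). Rings with fewer than 3 distinct vertices after collapsing
#' repeated consecutive vertices are rejected as malformed.
#'
#' @param path CSV file path.
#' @param masks mask vertex table.
#' @return `read_masks` returns the validated vertex table; `write_masks`
#'   returns `path` invisibly.
#' @export
read_masks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_masks(df)
  df$cell_id <- as.character(df$cell_id)
  for (r in mask_rings(df)) {
    d <- dedupe_ring(r$x, r$y)
    if (length(d$x) < 3L)
      abort_dx(sprintf("malformed polygon for cell %s (%s ring): fewer than 3 distinct vertices",
                       r$cell_id, r$ring),
               "duplexium_polygon_error")
    if (polygon_area(d$x, d$y) <= 0)
      abort_dx(sprintf("degenerate polygon for cell %s (%s ring)", r$cell_id, r$ring),
               "duplexium_polygon_error")
  }
  df
}

#' @rdname read_masks
#' @export
write_masks <- function(masks, path) {
  validate_masks(masks)
  utils::write.csv(masks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gene-panel files
#'
#' One gene symbol per line; duplicates within a panel are an error.
#'
#' @param path text file path.
#' @param genes character vector of gene symbols.
#' @param name panel name (e.g. `"V1"`, `"Prime"`).
#' @return `read_panel` returns a panel definition (see
#'   [panel_definition()]); `write_panel` returns `path` invisibly.
#' @export
read_panel <- function(path, name) {
  genes <- readLines(path)
  genes <- genes[nzchar(genes)]
  panel_definition(name, genes)
}

#' @rdname read_panel
#' @export
write_panel <- function(genes, path) {
  if (inherits(genes, "panel_definition")) genes <- genes$genes
  if (anyDuplicated(genes))
    abort_dx("duplicate genes in panel", "duplexium_schema_error")
  writeLines(genes, path)
  invisible(path)
}

#' Gene panel definition
#'
#' @param name panel name.
#' @param genes unique character vector of gene symbols.
#' @return A `panel_definition` (list with `name`, `genes`).
#' @export
panel_definition <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    abort_dx(sprintf("duplicate genes in panel %s: %s", name,
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")),
             "duplexium_schema_error")
  if (any(!nzchar(genes)))
    abort_dx("empty gene symbol in panel", "duplexium_schema_error")
  structure(list(name = as.character(name), genes = genes),
            class = "panel_definition")
}

#' Read and write landmark (anchor) pairs
#'
#' CSV with columns `x_moving`, `y_moving`, `x_fixed`, `y_fixed`
#' (micrometers), one row per anchor pair.
#'
#' @param path CSV file path.
#' @param landmarks landmark data.frame.
#' @return `read_landmarks` returns the data.frame; `write_landmarks`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_moving", "y_moving", "x_fixed", "y_fixed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_dx(sprintf("landmarks file missing column(s): %s",
                     paste(miss, collapse = ", ")),
             "duplexium_schema_error")
  df
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a sparse cell-by-gene matrix directory
#'
#' MatrixMarket coordinate layout (1-based indices) in the conventional
#' features x cells orientation: `matrix.mtx` plus `features.tsv` (one
#' panel-tagged feature name per line) and `cells.tsv` (one cell id per
#' line). In memory the counts are held cells x features.
#'
#' @param counts a cells x features sparse (or dense) matrix with dimnames,
#'   or a `cell_gene_matrix` view (its counts are written).
#' @param dir directory to create/write into.
#' @return `write_matrix` returns `dir` invisibly; `read_matrix` returns a
#'   cells x features `dgCMatrix` with dimnames.
#' @export
write_matrix <- function(counts, dir) {
  if (inherits(counts, "cell_gene_matrix")) counts <- counts$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_dx("counts must carry cell ids (rownames) and feature names (colnames)",
             "duplexium_schema_error")
  if (anyDuplicated(colnames(counts)))
    abort_dx("duplicate feature names", "duplexium_schema_error")
  if (anyDuplicated(rownames(counts)))
    abort_dx("duplicate cell ids", "duplexium_schema_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # write coordinate-real-general explicitly (features x cells) so the layout
  # never degrades to the pattern/symmetric MatrixMarket variants
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  lines <- c("%%MatrixMarket matrix coordinate real general",
             paste(ncol(m), nrow(m), length(m@x)),
             sprintf("%d %d %s", m@j + 1L, m@i + 1L,
                     vapply(m@x, format, "", digits = 15)))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  writeLines(rownames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  if (nrow(m) != length(feats) || ncol(m) != length(cells))
    abort_dx("matrix dimensions do not match features/cells files",
             "duplexium_schema_error")
  out <- methods::as(methods::as(Matrix::t(m), "CsparseMatrix"), "dMatrix")
  dimnames(out) <- list(cells, feats)
  out
}

#' Read and write per-cell metadata tables
#'
#' CSV keyed by `cell_id`; typically carries `sample_id`, geometry metrics and
#' per-view QC columns.
#'
#' @param metadata data.frame with a `cell_id` column.
#' @param path CSV file path.
#' @return `read_cell_metadata` returns the data.frame;
#'   `write_cell_metadata` returns `path` invisibly.
#' @export
write_cell_metadata <- function(metadata, path) {
  if (!"cell_id" %in% names(metadata))
    abort_dx("cell metadata needs a cell_id column", "duplexium_schema_error")
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_metadata
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df))
    abort_dx("cell metadata needs a cell_id column", "duplexium_schema_error")
  df$cell_id <- as.character(df$cell_id)
  df
}
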