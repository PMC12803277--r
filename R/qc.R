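#' Quality-control thresholds
#'
#' Thresholds for the two QC layers: the upstream transcript filter
#' (transcripts are kept when `qv >= qv_min`, overlap a segmented nucleus,
#' and carry a cell assignment) and the downstream cell filter (a cell is
#' retained when `n_counts >= min_counts`, `n_genes >= min_genes`,
#' `cell_area` lies within `cell_area_range` and
#' `nucleus_area >= nucleus_area_min`). All boundaries are inclusive, and all
#' areas are in square micrometers.
#'
#' The nuclear-overlap requirement is a flag because slide-level transcript
#' tallies include non-nuclear transcripts even though matrix building uses
#' only nucleus-partitioned ones.
#'
#' @param qv_min minimum decoding quality value kept (default 20).
#' @param require_nucleus_overlap,require_assignment transcript-filter flags.
#' @param min_counts,min_genes,cell_area_range,nucleus_area_min cell-filter
#'   thresholds.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(qv_min = 20,
                          require_nucleus_overlap = TRUE,
                          require_assignment = TRUE,
                          min_counts = 50L,
                          min_genes = 5L,
                          cell_area_range = c(5, 140),
                          nucleus_area_min = 3) {
  if (min_counts < 0L || min_genes < 0L)
    abort_dx("min_counts and min_genes must be >= 0", "duplexium_config_error")
  if (length(cell_area_range) != 2L || cell_area_range[1] >= cell_area_range[2])
    abort_dx("cell_area_range must be (low, high) with low < high",
             "duplexium_config_error")
  structure(list(qv_min = qv_min,
                 require_nucleus_overlap = isTRUE(require_nucleus_overlap),
                 require_assignment = isTRUE(require_assignment),
                 min_counts = as.integer(min_counts),
                 min_genes = as.integer(min_genes),
                 cell_area_range = as.numeric(cell_area_range),
                 nucleus_area_min = as.numeric(nucleus_area_min)),
            class = "qc_thresholds")
}

#' Upstream transcript-quality filter
#'
#' Removes transcripts that fail any required quality parameter: decoding
#' quality below `qv_min`, no nuclear overlap (when
#' `require_nucleus_overlap`), or no cell assignment (when
#' `require_assignment`; the sentinel is the literal `"UNASSIGNED"`).
#' Input order is preserved, the filter is idempotent, and each removed
#' transcript is tallied under exactly one reason, attributed in the order
#' `qv`, `nucleus`, `unassigned`.
#'
#' @param transcripts transcript data.frame (see [read_transcripts()]).
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (data.frame), `removed` (data.frame with a
#'   `reason` column) and `tally` (named integer vector over the three
#'   reasons; sums to the removed count).
#' @export
filter_transcripts <- function(transcripts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- nrow(transcripts)
  fail_qv <- transcripts$qv < thresholds$qv_min
  fail_nuc <- if (thresholds$require_nucleus_overlap)
    transcripts$overlaps_nucleus == 0L else rep(FALSE, n)
  fail_un <- if (thresholds$require_assignment)
    transcripts$cell_id == "UNASSIGNED" else rep(FALSE, n)
  reason <- rep(NA_character_, n)
  reason[fail_un] <- "unassigned"
  reason[fail_nuc] <- "nucleus"
  reason[fail_qv] <- "qv"
  removed <- !is.na(reason)
  tally <- c(qv = sum(reason == "qv", na.rm = TRUE),
             nucleus = sum(reason == "nucleus", na.rm = TRUE),
             unassigned = sum(reason == "unassigned", na.rm = TRUE))
  rem <- transcripts[removed, , drop = FALSE]
  if (nrow(rem)) rem$reason <- reason[removed]
  else rem$reason <- character(0)
  list(kept = transcripts[!removed, , drop = FALSE],
       removed = rem,
       tally = tally)
}
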