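#' Polygon area and centroid (shoelace formula)
#'
#' @param x,y vertex coordinates (micrometers), in order around the ring;
#'   the ring is closed implicitly.
#' @return `polygon_area`: area in square micrometers (nonnegative);
#'   `polygon_centroid`: length-2 numeric centroid.
#' @export
polygon_area <- function(x, y) {
  abs(signed_area(x, y))
}

signed_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(x, y) {
  a <- signed_area(x, y)
  if (abs(a) < 1e-12)
    abort_dx("degenerate polygon: zero area", "duplexium_polygon_error")
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  c(sum((x[j] + x) * cr), sum((y[j] + y) * cr)) / (6 * a)
}

#' Boundary-inclusive point-in-polygon test
#'
#' Even-odd (ray casting) rule, vectorised over points; points lying on a
#' polygon edge or vertex count as inside.
#'
#' @param px,py point coordinates.
#' @param vx,vy polygon vertex coordinates (closed implicitly).
#' @param eps absolute tolerance for the on-edge test.
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  np <- length(px)
  inside <- logical(np)
  on_edge <- logical(np)
  scale <- max(abs(c(vx, vy)), 1)
  tol <- eps * scale
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | (abs(cross) <= tol * max(abs(xj - xi), abs(yj - yi), 1) & within)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | on_edge
}

# split a mask vertex table into a list of per-cell rings
mask_rings <- function(masks) {
  validate_masks(masks)
  key <- paste(masks$cell_id, masks$ring, sep = "\r")
  idx <- split(seq_len(nrow(masks)), key)
  rings <- lapply(idx, function(i) {
    i <- i[order(masks$vertex_index[i])]
    list(cell_id = masks$cell_id[i[1]], ring = masks$ring[i[1]],
         x = masks$x[i], y = masks$y[i])
  })
  names(rings) <- NULL
  rings
}

validate_masks <- function(masks) {
  need <- c("cell_id", "ring", "vertex_index", "x", "y")
  miss <- setdiff(need, names(masks))
  if (length(miss))
    abort_dx(sprintf("mask table missing column(s): %s",
                     paste(miss, collapse = ", ")),
             "duplexium_schema_error")
  if (!all(masks$ring %in% c("cell", "nucleus")))
    abort_dx("mask `ring` must be \"cell\" or \"nucleus\"", "duplexium_schema_error")
  invisible(masks)
}

# drop consecutive duplicate vertices (closed ring); returns x/y
dedupe_ring <- function(x, y, tol = 1e-12) {
  n <- length(x)
  if (n == 0L) return(list(x = x, y = y))
  j <- c(n, seq_len(n - 1L))
  keep <- !(abs(x - x[j]) <= tol & abs(y - y[j]) <= tol)
  if (!any(keep)) keep[1] <- TRUE
  list(x = x[keep], y = y[keep])
}

#' Per-cell geometry metrics from segmentation masks
#'
#' Computes the shoelace area of each cell's boundary and nucleus rings and
#' the cell-boundary centroid. These feed the cell-level quality filters
#' (`cell_area`, `nucleus_area`) and centroid-based registration refinement.
#'
#' @param masks mask vertex table: columns `cell_id`, `ring` (`"cell"` or
#'   `"nucleus"`), `vertex_index`, `x`, `y` (micrometers).
#' @return data.frame with one row per cell: `cell_id`, `cell_area`,
#'   `nucleus_area` (0 when the nucleus ring is absent), `centroid_x`,
#'   `centroid_y`. Ordered by `cell_id`.
#' @export
compute_cell_metrics <- function(masks) {
  rings <- mask_rings(masks)
  ids <- sort(unique(masks$cell_id))
  out <- data.frame(cell_id = ids, cell_area = NA_real_, nucleus_area = 0,
                    centroid_x = NA_real_, centroid_y = NA_real_,
                    stringsAsFactors = FALSE)
  row_of <- match(vapply(rings, `[[`, "", "cell_id"), ids)
  for (k in seq_along(rings)) {
    r <- rings[[k]]
    d <- dedupe_ring(r$x, r$y)
    if (length(d$x) < 3L)
      abort_dx(sprintf("malformed polygon for cell %s (%s ring): fewer than 3 distinct vertices",
                       r$cell_id, r$ring),
               "duplexium_polygon_error")
    a <- polygon_area(d$x, d$y)
    if (a <= 0)
      abort_dx(sprintf("degenerate polygon for cell %s (%s ring): zero area",
                       r$cell_id, r$ring),
               "duplexium_polygon_error")
    i <- row_of[k]
    if (r$ring == "cell") {
      out$cell_area[i] <- a
      cen <- polygon_centroid(d$x, d$y)
      out$centroid_x[i] <- cen[1]
      out$centroid_y[i] <- cen[2]
    } else {
      out$nucleus_area[i] <- a
    }
  }
  if (anyNA(out$cell_area))
    abort_dx(sprintf("cell(s) without a cell ring: %s",
                     paste(out$cell_id[is.na(out$cell_area)], collapse = ", ")),
             "duplexium_polygon_error")
  rownames(out) <- NULL
  out
}

#' Assign points to segmentation masks (point-in-polygon)
#'
#' Re-implements the transcript-to-cell assignment step: every point receives
#' the `cell_id` of the (boundary-inclusive) cell polygon containing it, or
#' `"UNASSIGNED"` when it falls outside all cells, plus a nuclear-overlap flag
#' from containment in the owning cell's nucleus ring. When overlapping masks
#' both contain a point the tie is broken deterministically in favour of the
#' smaller cell area, then lexicographically smaller `cell_id`; the number of
#' such ties is reported.
#'
#' A uniform-grid spatial index over polygon bounding boxes keeps the search
#' sub-quadratic; results are identical to an exhaustive scan.
#'
#' @param points n x 2 matrix or data.frame with `x`/`y` columns
#'   (micrometers).
#' @param masks mask vertex table (see [compute_cell_metrics()]).
#' @return data.frame with `cell_id` (character, `"UNASSIGNED"` sentinel) and
#'   `overlaps_nucleus` (0/1) per point, with attribute `n_ties` giving the
#'   count of multi-containment ties resolved.
#' @export
assign_to_masks <- function(points, masks) {
  P <- as_xy_matrix(points)
  np <- nrow(P)
  out <- data.frame(cell_id = rep("UNASSIGNED", np),
                    overlaps_nucleus = rep(0L, np),
                    stringsAsFactors = FALSE)
  rings <- mask_rings(masks)
  cells <- Filter(function(r) r$ring == "cell", rings)
  nuclei <- Filter(function(r) r$ring == "nucleus", rings)
  if (length(cells) == 0L || np == 0L) {
    attr(out, "n_ties") <- 0L
    return(out)
  }
  nuc_of <- vapply(nuclei, `[[`, "", "cell_id")

  areas <- vapply(cells, function(r) polygon_area(r$x, r$y), 0)
  ord <- order(areas, vapply(cells, `[[`, "", "cell_id"))
  cells <- cells[ord]

  # uniform grid over the point cloud, bin size ~ median polygon bbox width
  bw <- stats::median(vapply(cells, function(r) diff(range(r$x)), 0))
  bh <- stats::median(vapply(cells, function(r) diff(range(r$y)), 0))
  bw <- max(bw, 1e-6); bh <- max(bh, 1e-6)
  x0 <- min(P[, 1]); y0 <- min(P[, 2])
  gx <- floor((P[, 1] - x0) / bw)
  gy <- floor((P[, 2] - y0) / bh)
  ng <- max(gx) + 2L
  key <- gx + gy * ng
  bins <- split(seq_len(np), key)

  assigned <- rep(NA_character_, np)
  n_ties <- 0L
  for (r in cells) {
    bx <- floor((range(r$x) - x0) / bw)
    by <- floor((range(r$y) - y0) / bh)
    kk <- as.character(outer(seq(bx[1], bx[2]), seq(by[1], by[2]) * ng, "+"))
    cand <- unlist(bins[intersect(kk, names(bins))], use.names = FALSE)
    if (!length(cand)) next
    inb <- P[cand, 1] >= min(r$x) & P[cand, 1] <= max(r$x) &
      P[cand, 2] >= min(r$y) & P[cand, 2] <= max(r$y)
    cand <- cand[inb]
    if (!length(cand)) next
    hit <- cand[point_in_polygon(P[cand, 1], P[cand, 2], r$x, r$y)]
    if (!length(hit)) next
    tie <- !is.na(assigned[hit])
    n_ties <- n_ties + sum(tie)
    new <- hit[!tie]          # smaller-area polygon was processed first
    assigned[new] <- r$cell_id
  }
  hit_idx <- which(!is.na(assigned))
  out$cell_id[hit_idx] <- assigned[hit_idx]

  # nuclear overlap within the owning cell only
  if (length(nuclei) && length(hit_idx)) {
    by_cell <- split(hit_idx, assigned[hit_idx])
    for (cid in names(by_cell)) {
      k <- match(cid, nuc_of)
      if (is.na(k)) next
      r <- nuclei[[k]]
      idx <- by_cell[[cid]]
      inn <- point_in_polygon(P[idx, 1], P[idx, 2], r$x, r$y)
      out$overlaps_nucleus[idx[inn]] <- 1L
    }
  }
  attr(out, "n_ties") <- n_ties
  out
}
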