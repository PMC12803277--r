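#' 2-D affine transform between two imaging runs' coordinate frames
#'
#' When the same slide is imaged in two sequential instrument runs, re-seating
#' the slide cassette shifts the stage coordinate system slightly. The map
#' between the two frames is modelled as a linear transformation
#' `p' = L p + t` with `L` a 2x2 matrix and `t` a translation in micrometers.
#' Under `model = "similarity"` the linear part is constrained to
#' `s * R` (uniform scale times rotation, no reflection), which matches the
#' rigid-like nature of a cassette re-seating; `model = "affine"` allows
#' anisotropic scale and shear.
#'
#' @param linear 2x2 numeric matrix, the linear component.
#' @param translation numeric length-2 translation in micrometers.
#' @param model `"similarity"` or `"affine"`.
#' @param rms residual root-mean-square distance (um) from the fit that
#'   produced the transform, or `NA` for a constructed transform.
#' @return An object of class `affine_transform`.
#' @seealso [estimate_transform()], [apply_transform()], [refine_by_centroids()]
#' @export
affine_transform <- function(linear = diag(2), translation = c(0, 0),
                             model = c("affine", "similarity"),
                             rms = NA_real_) {
  model <- match.arg(model)
  linear <- matrix(as.numeric(linear), 2L, 2L)
  translation <- as.numeric(translation)
  if (length(translation) != 2L || any(!is.finite(translation)))
    abort_dx("`translation` must be two finite numbers", "duplexium_transform_error")
  if (any(!is.finite(linear)))
    abort_dx("`linear` must be finite", "duplexium_transform_error")
  if (abs(det(linear)) < 1e-12)
    abort_dx("linear component is singular", "duplexium_transform_error")
  if (model == "similarity") {
    if (det(linear) < 0)
      abort_dx("similarity transforms exclude reflections", "duplexium_transform_error")
    s <- sqrt(det(linear))
    if (max(abs(crossprod(linear / s) - diag(2))) > 1e-6)
      abort_dx("for model = \"similarity\" the linear part must be scale x rotation",
               "duplexium_transform_error")
  }
  structure(list(linear = linear, translation = translation,
                 model = model, rms = rms),
            class = "affine_transform")
}

#' Identity transform
#' @param model transform model tag.
#' @return An `affine_transform` that maps every point to itself.
#' @export
identity_transform <- function(model = c("similarity", "affine")) {
  affine_transform(diag(2), c(0, 0), match.arg(model))
}

#' Build a similarity transform from rotation / scale / translation
#'
#' @param rotation_deg rotation angle, degrees counter-clockwise.
#' @param scale uniform scale factor (> 0).
#' @param translation length-2 translation, micrometers.
#' @return An `affine_transform` with `model = "similarity"`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1,
                                 translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  L <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  affine_transform(L, translation, model = "similarity")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform: %s>\n", x$model))
  cat(sprintf("  linear      [%9.6f %9.6f; %9.6f %9.6f]\n",
              x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2]))
  cat(sprintf("  translation (%.4f, %.4f) um\n",
              x$translation[1], x$translation[2]))
  if (x$model == "similarity")
    cat(sprintf("  scale %.6f, rotation %.4f deg\n",
                transform_scale(x), transform_rotation_deg(x)))
  if (!is.na(x$rms)) cat(sprintf("  fit residual RMS %.4g um\n", x$rms))
  invisible(x)
}

#' Scale and rotation of a similarity transform
#' @param transform an `affine_transform`.
#' @return `transform_scale`: the uniform scale factor;
#'   `transform_rotation_deg`: the rotation angle in degrees.
#' @export
transform_scale <- function(transform) sqrt(abs(det(transform$linear)))

#' @rdname transform_scale
#' @export
transform_rotation_deg <- function(transform) {
  s <- transform_scale(transform)
  atan2(transform$linear[2, 1] / s, transform$linear[1, 1] / s) * 180 / pi
}

#' Apply a transform to points or to polygon masks
#'
#' Maps every coordinate as `L p + t`. For a mask vertex table the `x`/`y`
#' columns are replaced and everything else (cell ids, ring labels, vertex
#' order, hence polygon topology) is preserved; polygon areas scale by
#' `|det(L)|`.
#'
#' @param transform an `affine_transform`.
#' @param x an n x 2 matrix of points, or a data.frame with `x` and `y`
#'   columns (e.g. a transcript table or a mask vertex table).
#' @return Object of the same shape as `x` with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "affine_transform"))
  if (is.data.frame(x)) {
    p <- as_xy_matrix(x)
    q <- transform_points(transform, p)
    x$x <- q[, 1]
    x$y <- q[, 2]
    return(x)
  }
  transform_points(transform, as_xy_matrix(x))
}

transform_points <- function(transform, p) {
  q <- p %*% t(transform$linear)
  q[, 1] <- q[, 1] + transform$translation[1]
  q[, 2] <- q[, 2] + transform$translation[2]
  q
}

#' Invert / compose transforms
#'
#' `invert_transform(T)` returns the map with `T(invert_transform(T)(p)) = p`;
#' `compose_transforms(a, b)` returns the map `p -> a(b(p))`.
#'
#' @param transform,a,b `affine_transform` objects.
#' @return An `affine_transform`.
#' @export
invert_transform <- function(transform) {
  Linv <- solve(transform$linear)
  affine_transform(Linv, -Linv %*% transform$translation,
                   model = transform$model)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  model <- if (a$model == "similarity" && b$model == "similarity")
    "similarity" else "affine"
  affine_transform(a$linear %*% b$linear,
                   as.numeric(a$linear %*% b$translation) + a$translation,
                   model = model)
}

#' Estimate the inter-run transform from landmark pairs
#'
#' Least-squares fit of the linear map minimising
#' `sum_i || T(moving_i) - fixed_i ||^2` over paired anchor points placed on
#' corresponding landmarks in the two runs. For `model = "similarity"` the
#' closed-form Procrustes (Umeyama) solution is used (rotation + uniform
#' scale + translation, reflections excluded); for `model = "affine"` an
#' ordinary least-squares fit of all six parameters.
#'
#' @param landmarks a data.frame with columns `x_moving`, `y_moving`,
#'   `x_fixed`, `y_fixed` (micrometers), one row per anchor pair.
#' @param model `"similarity"` (default; needs >= 2 distinct pairs) or
#'   `"affine"` (needs >= 3 non-collinear pairs).
#' @return An `affine_transform` carrying the residual RMS in `$rms`.
#' @export
estimate_transform <- function(landmarks, model = c("similarity", "affine")) {
  model <- match.arg(model)
  lm_cols <- c("x_moving", "y_moving", "x_fixed", "y_fixed")
  if (!all(lm_cols %in% names(landmarks)))
    abort_dx(sprintf("landmarks must have columns %s",
                     paste(lm_cols, collapse = ", ")),
             "duplexium_schema_error")
  M <- cbind(landmarks$x_moving, landmarks$y_moving)
  F_ <- cbind(landmarks$x_fixed, landmarks$y_fixed)
  n <- nrow(M)
  if (model == "similarity") {
    if (n < 2L)
      abort_dx("similarity fit needs at least 2 landmark pairs",
               "duplexium_rank_error")
    mu_m <- colMeans(M); mu_f <- colMeans(F_)
    Mc <- sweep(M, 2, mu_m); Fc <- sweep(F_, 2, mu_f)
    var_m <- sum(Mc^2) / n
    if (var_m < 1e-12)
      abort_dx("landmark moving points are coincident; similarity fit is rank-deficient",
               "duplexium_rank_error")
    S <- crossprod(Fc, Mc) / n
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    if (d == 0) d <- 1
    D <- diag(c(1, d))
    R <- sv$u %*% D %*% t(sv$v)
    s <- sum(sv$d * c(1, d)) / var_m
    if (s <= 1e-12)
      abort_dx("degenerate landmark configuration (zero scale)",
               "duplexium_rank_error")
    L <- s * R
    t_ <- as.numeric(mu_f - L %*% mu_m)
  } else {
    if (n < 3L)
      abort_dx("affine fit needs at least 3 landmark pairs", "duplexium_rank_error")
    X <- cbind(M, 1)
    qx <- qr(X)
    if (qx$rank < 3L)
      abort_dx("landmarks are collinear; affine fit is rank-deficient",
               "duplexium_rank_error")
    coef <- qr.coef(qx, F_)
    L <- t(coef[1:2, , drop = FALSE])
    t_ <- as.numeric(coef[3, ])
  }
  out <- affine_transform(L, t_, model = model)
  resid <- transform_points(out, M) - F_
  out$rms <- sqrt(mean(rowSums(resid^2)))
  out
}

# greedy one-to-one nearest-neighbour matching within a cutoff radius;
# candidate pairs are taken in ascending distance order
match_nearest <- function(P, F_, cutoff) {
  d2 <- outer(P[, 1], F_[, 1], "-")^2 + outer(P[, 2], F_[, 2], "-")^2
  cand <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_i <- logical(nrow(P)); used_j <- logical(nrow(F_))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  list(i = cand[, 1], j = cand[, 2],
       dist = sqrt(d2[cand]))
}

# rigid (rotation + translation, scale = 1) Procrustes fit
estimate_rigid <- function(M, F_) {
  mu_m <- colMeans(M); mu_f <- colMeans(F_)
  Mc <- sweep(M, 2, mu_m); Fc <- sweep(F_, 2, mu_f)
  S <- crossprod(Fc, Mc)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  affine_transform(R, as.numeric(mu_f - R %*% mu_m), model = "similarity")
}

#' Fine-scale refinement of a registration by iterative closest point
#'
#' Landmark fits get the two frames roughly aligned; residual misalignment of
#' a fraction of a cell diameter is then removed by matching the transformed
#' moving-run cell centroids to the fixed-run centroids. Each iteration (a)
#' greedily matches each transformed moving centroid to its nearest unmatched
#' fixed centroid within `cutoff` micrometers (ascending-distance, one-to-one)
#' and (b) estimates a rigid (rotation + translation) correction from the
#' matched pairs. Iteration stops when the mean matched distance improves by
#' less than `tol` or after `max_iter` rounds; the returned transform is the
#' one with the smallest mean matched distance seen, so refinement never
#' worsens the alignment.
#'
#' @param transform0 initial `affine_transform` (e.g. from
#'   [estimate_transform()]); must be roughly correct for nearest-neighbour
#'   matching to be meaningful.
#' @param moving_centroids,fixed_centroids n x 2 matrices or data.frames with
#'   `x`/`y` columns; cell centroids in the moving and fixed frames. The two
#'   sets need not be the same length (cells may be present in only one run).
#' @param cutoff matching radius, micrometers (default 15, about one cell
#'   diameter).
#' @param max_iter,tol iteration cap and mean-distance improvement tolerance
#'   (um).
#' @return The refined `affine_transform`, with attributes `n_iter`,
#'   `mean_matched_dist`, `n_matched` and `unmatched_frac` (fraction of
#'   moving centroids left unmatched). If no centroid pair falls within
#'   `cutoff`, an error of class `duplexium_refinement_error` is signalled
#'   whose condition carries the initial transform in `$transform`.
#' @export
refine_by_centroids <- function(transform0, moving_centroids, fixed_centroids,
                                cutoff = 15, max_iter = 50L, tol = 1e-4) {
  stopifnot(inherits(transform0, "affine_transform"))
  M <- as_xy_matrix(moving_centroids)
  F_ <- as_xy_matrix(fixed_centroids)
  if (nrow(M) == 0L || nrow(F_) == 0L)
    stop(errorCondition("no centroids to refine against",
                        transform = transform0,
                        class = c("duplexium_refinement_error", "duplexium_error")))
  cur <- transform0
  m <- match_nearest(transform_points(cur, M), F_, cutoff)
  if (length(m$i) == 0L)
    stop(errorCondition(
      sprintf("no centroid matches within cutoff = %g um; initial transform attached",
              cutoff),
      transform = transform0,
      class = c("duplexium_refinement_error", "duplexium_error")))
  cur_dist <- mean(m$dist)
  best <- cur; best_dist <- cur_dist; best_m <- m
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    P <- transform_points(cur, M)
    corr <- estimate_rigid(P[m$i, , drop = FALSE], F_[m$j, , drop = FALSE])
    cand <- compose_transforms(corr, cur)
    m2 <- match_nearest(transform_points(cand, M), F_, cutoff)
    if (length(m2$i) == 0L) break
    cand_dist <- mean(m2$dist)
    if (cand_dist < best_dist) {
      best <- cand; best_dist <- cand_dist; best_m <- m2
    }
    if (cur_dist - cand_dist < tol) break
    cur <- cand; cur_dist <- cand_dist; m <- m2
  }
  structure(best,
            n_iter = n_iter,
            mean_matched_dist = best_dist,
            n_matched = length(best_m$i),
            unmatched_frac = 1 - length(best_m$i) / nrow(M))
}

#' Write / read a transform as JSON
#'
#' The on-disk layout is `{"linear": [row-major 4 numbers], "translation":
#' [2], "model": "...", "residual_rms": number|null}`.
#'
#' @param transform an `affine_transform`.
#' @param path file path for the JSON document.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the `affine_transform`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  obj <- list(linear = as.numeric(t(transform$linear)),
              translation = transform$translation,
              model = transform$model,
              residual_rms = if (is.na(transform$rms)) NULL else transform$rms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- affine_transform(matrix(obj$linear, 2, 2, byrow = TRUE),
                          obj$translation, model = obj$model)
  out$rms <- if (is.null(obj$residual_rms)) NA_real_ else obj$residual_rms
  out
}
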