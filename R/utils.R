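# internal helpers shared across modules

# classed error so callers can distinguish contract violations
abort_dx <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "duplexium_error")))
}

# evaluate `code` under a temporary RNG state; global stream untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

as_xy_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x)))
      abort_dx("point data.frame needs `x` and `y` columns", "duplexium_schema_error")
    x <- cbind(x$x, x$y)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    abort_dx("points must be an n x 2 matrix or a data.frame with x/y", "duplexium_schema_error")
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
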