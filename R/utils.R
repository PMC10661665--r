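#' @keywords internal
"_PACKAGE"

## Coordinate convention used throughout the package:
## times are milliseconds from record start, sample k (1-based) sits at
## (k - 1) * 1000 / fs ms, and windows are half-open [start, end).

#' Convert a time in ms to the nearest 1-based sample index
#' @noRd
time_to_index <- function(t_ms, fs) {
  as.integer(round(t_ms * fs / 1000)) + 1L
}

#' Convert a 1-based sample index to time in ms
#' @noRd
index_to_time <- function(idx, fs) {
  (idx - 1) * 1000 / fs
}

#' Evaluate code with a local RNG seed, restoring global RNG state
#'
#' Every stochastic operation in the package routes its randomness through
#' this helper so that a call is reproducible from its own `seed` argument
#' and never perturbs (or depends on) the caller's RNG state.
#' @noRd
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}
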