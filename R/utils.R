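`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All generator functions route their randomness through this helper so that
#' a given seed reproduces outputs bit-for-bit and callers' RNG streams are
#' left untouched.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Greedy minimum-separation filter: keep each time that is at least `min_gap`
# after the last kept one. `times` must be sorted increasing. Returns a
# logical keep mask.
dedup_mask <- function(times, min_gap) {
  n <- length(times)
  keep <- logical(n)
  last <- -Inf
  for (k in seq_len(n)) {
    if (times[k] - last >= min_gap) {
      keep[k] <- TRUE
      last <- times[k]
    }
  }
  keep
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
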