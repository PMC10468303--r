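#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards. All stochastic operations in the package route
#' through this helper so that a spec plus a seed is fully reproducible and
#' no global state leaks between calls.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a stage-tagged error message
#' @keywords internal
stop_stage <- function(stage, ...) {
  stop(sprintf("[stage %s] %s", stage, paste0(..., collapse = "")), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
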