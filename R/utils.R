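#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never disturb the user's stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a global seed and a stage label
#'
#' Deterministic expansion of one pipeline seed into independent per-stage
#' seeds. Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer child seed.
#' @keywords internal
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

# raw MAD: median absolute deviation from the median, no consistency constant
mad_raw <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

# robust z against median and 1.4826-scaled MAD (Gaussian-consistent)
robust_z <- function(x) {
  m <- stats::median(x, na.rm = TRUE)
  s <- 1.4826 * mad_raw(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
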