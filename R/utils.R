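# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so that seeded model fitting
#' and simulation never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Percentile 95% interval of a vector of per-iteration metric values.
ci_percentile <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# Full-precision numeric formatting so TSV round trips are bit-exact.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
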