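# Internal helpers shared across modules.

#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (design, cohort, sampler chains, BMS Monte Carlo), so that any
#' artifact can be regenerated in isolation.
#'
#' @param seed Master seed (integer).
#' @param stream Character label of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(1, "design")
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (v in utf8ToInt(stream)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 16807 + 12345) %% 2147483647)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log density of a normal distribution truncated to the rating scale
#'
#' Observation model for expectation ratings: a normal density with the
#' model-predicted rating as location, truncated to `[0, 100]`.
#'
#' @param x Observed rating(s).
#' @param mean Predicted rating(s).
#' @param sd Observation noise (percentile units, > 0).
#' @return Log density, `-Inf` outside `[0, 100]`.
#' @export
dtnorm_rating <- function(x, mean, sd) {
  stopifnot(all(sd > 0))
  z <- pnorm(100, mean, sd) - pnorm(0, mean, sd)
  out <- dnorm(x, mean, sd, log = TRUE) - log(z)
  out[x < 0 | x > 100] <- -Inf
  out
}

# Draw from the truncated rating-scale normal by inverse CDF (vectorised).
rtnorm_rating <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(100, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

assert_rating <- function(x, what = "rating") {
  bad <- which(!is.finite(x) | x < 0 | x > 100)
  if (length(bad)) {
    stop(sprintf("%s out of [0, 100] at position %d (value %s)",
                 what, bad[1], format(x[bad[1]])), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
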