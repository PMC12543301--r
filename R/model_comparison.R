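# Out-of-sample model evidence and population-level model selection.
#
# Per participant and model, leave-one-trial-out predictive density is
# estimated from the posterior draws by Pareto-smoothed importance sampling
# (PSIS): the largest 20% of importance ratios per trial are replaced by
# expected order statistics of a generalized Pareto distribution fitted to
# them, and the tail-shape estimate k-hat diagnoses reliability. The
# resulting evidence matrix feeds a random-effects Bayesian model selection:
# each participant's generating model is treated as a draw from a population
# distribution with a Dirichlet prior, updated variationally; exceedance
# probabilities are integrated by Monte Carlo, and the Bayesian omnibus risk
# (the posterior probability that all model frequencies are equal) protects
# them against chance-level heterogeneity.

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' @param x A `loop_fit` (uses its stored pointwise log-likelihood matrix) or
#'   a draws-by-trials log-likelihood matrix.
#' @param session Optional session label (`"T1"` or `"T2"`) restricting the
#'   evaluation to that session's trials (only for `loop_fit` input).
#' @param tail_frac Fraction of importance ratios smoothed in the upper tail
#'   (capped at `3 * sqrt(n_draws)` ratios).
#' @param khat_warn Tail-shape threshold above which a trial's estimate is
#'   counted as unreliable.
#' @param ... Passed between methods.
#' @return A `loop_loo` object: pointwise tibble (`elpd`, `khat`, in-sample
#'   `lpd`), totals, and the fraction of trials with k-hat above the
#'   threshold.
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @rdname psis_loo
#' @export
psis_loo.loop_fit <- function(x, session = NULL, ...) {
  if (is.null(x$loglik))
    stop("fit was slimmed; its log-likelihood matrix is gone", call. = FALSE)
  ll <- x$loglik
  meta <- x$trials
  if (!is.null(session)) {
    keep <- meta$session == session
    ll <- ll[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  out <- psis_loo.matrix(ll, ...)
  out$pointwise <- dplyr::bind_cols(
    dplyr::select(meta, dplyr::any_of(c("participant", "session", "agent",
                                        "ability", "category", "trial"))),
    out$pointwise)
  out$model <- x$model
  out$participant <- x$participant
  out
}

#' @rdname psis_loo
#' @export
psis_loo.matrix <- function(x, tail_frac = 0.2, khat_warn = 0.7, ...) {
  S <- nrow(x)
  if (S < 100) stop("need at least 100 draws for PSIS-LOO", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite log-likelihoods", call. = FALSE)
  n <- ncol(x)
  elpd <- khat <- lpd <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    ll <- x[, i]
    lpd[i] <- log_sum_exp(ll) - log(S)
    sm <- psis_smooth(-ll, tail_frac)
    if (is.na(sm$khat)) flagged[i] <- TRUE
    lw <- sm$lw
    elpd[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
    khat[i] <- sm$khat
  }
  structure(list(
    pointwise = tibble::tibble(elpd = elpd, khat = khat, lpd = lpd),
    elpd = sum(elpd), lpd = sum(lpd),
    frac_khat_high = if (n) mean(khat > khat_warn, na.rm = TRUE) else NA_real_,
    zero_variance = flagged, n_trials = n, n_draws = S
  ), class = "loop_loo")
}

#' @export
print.loop_loo <- function(x, ...) {
  cat(sprintf("<loop_loo> elpd = %.2f over %d trials (%.1f%% khat > 0.7)\n",
              x$elpd, x$n_trials, 100 * x$frac_khat_high))
  invisible(x)
}

# Smooth one trial's log importance ratios: fit a generalized Pareto to the
# upper tail_frac of the ratios and replace them by its expected order
# statistics, truncated at the raw maximum.
psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  lw <- lw - max(lw)
  if (sd(lw) < 1e-12) return(list(lw = lw, khat = NA_real_))
  # cap the smoothed tail at 3*sqrt(S): smoothing a full fifth of large
  # samples visibly biases elpd upward against exact refit LOO
  M <- ceiling(min(tail_frac * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, khat = NA_real_))
  ord <- order(lw, decreasing = TRUE)
  tail_idx <- ord[seq_len(M)]
  cut_lw <- max(lw[ord[(M + 1):S]])
  exceed <- exp(lw[tail_idx]) - exp(cut_lw)
  if (all(exceed <= 0) || sd(exceed) < 1e-14)
    return(list(lw = lw, khat = NA_real_))
  fit <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fit$k)) return(list(lw = lw, khat = NA_real_))
  p <- (rank(lw[tail_idx], ties.method = "first") - 0.5) / M
  q <- qgpd(p, fit$k, fit$sigma)
  sm <- log(exp(cut_lw) + q)
  lw[tail_idx] <- pmin(sm, 0) # truncate at the raw maximum weight
  list(lw = lw, khat = fit$k)
}

# Generalized Pareto fit by the Zhang & Stephens (2009) profile posterior.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), 0)
  L <- n * (log(bs / ks) + ks - 1)
  w <- exp(L - log_sum_exp(L))
  b <- sum(bs * w)
  # convert to the tail-shape convention where k > 0 means a heavy tail
  k <- mean(log1p(-b * x))
  list(k = k, sigma = -k / b)
}

# Generalized Pareto quantile function (Vehtari sign convention: k > 0 means
# a heavy tail).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' Assemble a participants-by-models evidence matrix of LOO scores
#'
#' @param fits A tibble from [fit_cohort()] (columns `participant`, `model`,
#'   `fit`).
#' @param session Optional session restriction passed to [psis_loo()].
#' @return A numeric matrix (rows = participants, columns = models) of
#'   summed PSIS-LOO scores.
#' @export
loo_evidence <- function(fits, session = NULL) {
  col <- if (is.null(session)) "elpd" else paste0("elpd_", session)
  scores <- if (col %in% names(fits)) fits[[col]] else
    purrr::map_dbl(fits$fit, function(f) psis_loo(f, session = session)$elpd)
  tb <- tibble::tibble(participant = fits$participant, model = fits$model,
                       elpd = scores) |>
    tidyr::pivot_wider(names_from = "model", values_from = "elpd")
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$participant
  m
}

#' Random-effects Bayesian model selection
#'
#' Treats each participant's best-fitting model as a draw from a population
#' distribution over models with a Dirichlet(1, ..., 1) prior, estimated by
#' variational updates iterated to convergence of the free energy. Reports
#' expected model frequencies, exceedance probabilities (Monte-Carlo
#' integration over the Dirichlet posterior), the Bayesian omnibus risk (the
#' posterior probability of equal model frequencies, from the free-energy
#' comparison against the null model), and protected exceedance
#' probabilities `pxp = (1 - BOR) * xp + BOR / K`.
#'
#' @param evidence Participants-by-models matrix of log evidence (summed
#'   PSIS-LOO scores).
#' @param alpha0 Dirichlet prior count per model.
#' @param n_mc Monte-Carlo draws for the exceedance integration.
#' @param seed Seed for the Monte-Carlo integration.
#' @param tol Convergence tolerance on the free-energy change.
#' @param max_iter Iteration cap for the variational loop.
#' @return A `loop_bms` object with a per-model tibble (`frequency`, `xp`,
#'   `pxp`), the Dirichlet posterior counts, the omnibus risk `bor`, and the
#'   per-participant model attribution matrix.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_mc = 1e5, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  evidence <- as.matrix(evidence)
  P <- nrow(evidence); K <- ncol(evidence)
  if (K < 2) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(evidence))) stop("non-finite evidence", call. = FALSE)
  flags <- if (P < 2) "single_participant_low_power" else character(0)
  models <- colnames(evidence) %||% paste0("model", seq_len(K))

  a0 <- rep(alpha0, K)
  a <- a0 + P / K
  f_old <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(a) - digamma(sum(a)), "+")
    z <- exp(lw - apply(lw, 1, log_sum_exp))
    a <- a0 + colSums(z)
    f <- bms_free_energy(evidence, z, a, a0)
    if (is.finite(f_old) && abs(f - f_old) < tol) break
    f_old <- f
  }
  # Null model: every participant draws uniformly from equal frequencies.
  f0 <- sum(apply(evidence, 1, log_sum_exp) - log(K))
  bor <- 1 / (1 + exp(f - f0))

  set.seed(sub_seed(seed, "bms-exceedance"))
  g <- matrix(rgamma(n_mc * K, shape = rep(a, each = n_mc)), n_mc, K)
  xp <- tabulate(max.col(g, ties.method = "random"), K) / n_mc
  pxp <- (1 - bor) * xp + bor / K

  structure(list(
    table = tibble::tibble(model = models, frequency = a / sum(a),
                           xp = xp, pxp = pxp),
    alpha = setNames(a, models), bor = bor, free_energy = f,
    null_free_energy = f0, attribution = z, n_participants = P,
    flags = flags
  ), class = "loop_bms")
}

bms_free_energy <- function(evidence, z, a, a0) {
  dg <- digamma(a) - digamma(sum(a))
  e_lik <- sum(z * evidence)
  e_pi <- sum(sweep(z, 2, dg, "*"))
  ent_z <- -sum(z[z > 0] * log(z[z > 0]))
  kl_dir <- lgamma(sum(a)) - sum(lgamma(a)) -
    (lgamma(sum(a0)) - sum(lgamma(a0))) +
    sum((a - a0) * dg)
  e_lik + e_pi + ent_z - kl_dir
}

#' @export
print.loop_bms <- function(x, ...) {
  cat(sprintf("<loop_bms> %d participants, %d models, BOR = %.3g\n",
              x$n_participants, nrow(x$table), x$bor))
  print(x$table)
  invisible(x)
}

#' Fixed-effect model comparison from summed LOO scores
#'
#' Sums each model's PSIS-LOO scores over participants and reports the
#' difference to the best model (0 for the best, negative otherwise).
#'
#' @param evidence Participants-by-models matrix of LOO scores.
#' @return A tibble with `model`, `elpd_sum`, `delta_best`, sorted best
#'   first.
#' @export
fixed_effect_compare <- function(evidence) {
  evidence <- as.matrix(evidence)
  sums <- colSums(evidence)
  tibble::tibble(model = colnames(evidence) %||% paste0("model", seq_along(sums)),
                 elpd_sum = unname(sums),
                 delta_best = unname(sums - max(sums))) |>
    dplyr::arrange(dplyr::desc(.data$elpd_sum))
}
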