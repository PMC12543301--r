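# Per-participant Bayesian estimation.
#
# Every model is fitted to one participant's trials at a time. Bounded
# parameters are sampled on an unconstrained scale (logit for rates, weights
# and starting values scaled to the unit interval, log for the observation
# noise) with flat priors on the natural scale for the bounded parameters and
# a half-normal(20) prior on sigma. The canonical backend is an adaptive
# random-walk Metropolis sampler honouring the draw-count contract (3 chains,
# 1,000 burn-in iterations, 3,400 iterations in total per chain, thinned by
# 3, leaving 2,400 kept draws overall); a deterministic MAP + Laplace
# backend is provided as a fast, clearly non-canonical alternative for large
# recovery studies.

#' Configure a participant-level fit
#'
#' Defaults follow the canonical sampling scheme: three chains, 1,000 burn-in
#' iterations each, 2,400 post-thinning draws in total (800 per chain, thin
#' 3, hence 3,400 iterations per chain overall).
#'
#' @param n_chains Number of MCMC chains.
#' @param n_burnin Burn-in iterations per chain.
#' @param n_kept Total kept draws across chains (after thinning).
#' @param thin Thinning factor.
#' @param seed Master seed; chain and initialisation substreams derive from
#'   it.
#' @param sampler `"mcmc"` (adaptive Metropolis, canonical) or `"map"`
#'   (posterior mode + Laplace draws; deterministic and fast, no convergence
#'   diagnostics).
#' @param sigma_nd Scale of the feedback-discounting density (percentile
#'   units).
#' @param prior_sigma_scale Scale of the half-normal prior on the observation
#'   noise.
#' @param n_starts Optimiser restarts for the MAP backend.
#' @param rhat_max Convergence threshold; any split-R-hat above it flags the
#'   fit.
#' @return A `loop_fit_config` list.
#' @export
fit_config <- function(n_chains = 3L, n_burnin = 1000L, n_kept = 2400L,
                       thin = 3L, seed = 1L, sampler = c("mcmc", "map"),
                       sigma_nd = 17, prior_sigma_scale = 20,
                       n_starts = 4L, rhat_max = 1.05) {
  sampler <- match.arg(sampler)
  stopifnot(n_chains >= 1, n_burnin >= 0, n_kept >= n_chains, thin >= 1,
            n_kept %% n_chains == 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_kept = as.integer(n_kept), thin = as.integer(thin),
                 seed = seed, sampler = sampler, sigma_nd = sigma_nd,
                 prior_sigma_scale = prior_sigma_scale,
                 n_starts = as.integer(n_starts), rhat_max = rhat_max),
            class = "loop_fit_config")
}

# ---- parameter transforms ---------------------------------------------------

# Parameter block layout on the unconstrained scale: logit for (0,1) rates
# and weights, logit of value/100 for percentile-scale parameters, log for
# sigma.
par_kind <- function(spec) {
  kinds <- c(rep("unit", length(spec$alpha_names)),
             rep("unit", length(spec$w_names)),
             rep("pct", length(spec$sv_names)), "sigma")
  setNames(kinds, spec$par_names)
}

to_natural <- function(z, kinds) {
  th <- z
  th[kinds == "unit"] <- plogis(z[kinds == "unit"])
  th[kinds == "pct"] <- 100 * plogis(z[kinds == "pct"])
  th[kinds == "sigma"] <- exp(z[kinds == "sigma"])
  th
}

to_unconstrained <- function(theta, kinds) {
  z <- theta
  z[kinds == "unit"] <- qlogis(pmin(1 - 1e-9, pmax(1e-9, theta[kinds == "unit"])))
  z[kinds == "pct"] <- qlogis(pmin(1 - 1e-9, pmax(1e-9, theta[kinds == "pct"] / 100)))
  z[kinds == "sigma"] <- log(theta[kinds == "sigma"])
  z
}

# Log prior + log Jacobian on the unconstrained scale (flat priors on the
# natural scale for bounded parameters; half-normal on sigma).
log_prior_jac <- function(z, kinds, prior_sigma_scale) {
  lp <- 0
  u <- z[kinds %in% c("unit", "pct")]
  p <- plogis(u)
  lp <- lp + sum(log(p) + log1p(-p))
  s <- exp(z[kinds == "sigma"])
  lp + dnorm(s, 0, prior_sigma_scale, log = TRUE) + log(2) + z[kinds == "sigma"]
}

# Draw initial values from the priors (sigma from the half-normal).
draw_init <- function(spec, kinds, prior_sigma_scale) {
  theta <- numeric(length(kinds))
  theta[kinds == "unit"] <- runif(sum(kinds == "unit"))
  theta[kinds == "pct"] <- runif(sum(kinds == "pct"), 0, 100)
  theta[kinds == "sigma"] <- abs(rnorm(1, 0, prior_sigma_scale)) + 0.5
  setNames(theta, names(kinds))
}

# ---- fitting ---------------------------------------------------------------

#' Fit one participant's trials under one model
#'
#' Samples the posterior of all free parameters given the participant's
#' trial table and returns kept draws, posterior summaries (mean, sd,
#' split-R-hat, effective sample size), the draws-by-trials pointwise
#' log-likelihood matrix used for model comparison, and convergence flags.
#' Non-convergence (any R-hat above the threshold) and degenerate data
#' (constant ratings) are flagged, never silently accepted.
#'
#' @param model Model id string or [model_spec()].
#' @param trials Trial tibble for one participant (one or both sessions; a
#'   single session is flagged).
#' @param config A [fit_config()].
#' @return A `loop_fit` object.
#' @export
fit_participant <- function(model, trials, config = fit_config()) {
  spec <- if (inherits(model, "loop_model")) model else model_spec(model)
  kinds <- par_kind(spec)
  d <- length(kinds)
  if (nrow(trials)) assert_rating(trials$expectation, "expectation")
  flags <- character(0)
  if (nrow(trials) && length(unique(round(trials$expectation, 6))) == 1L)
    flags <- c(flags, "degenerate_constant_ratings")
  if (nrow(trials) && length(unique(trials$session)) < 2L)
    flags <- c(flags, "single_session")

  # precomputed likelihood context: sorted trials + parameter block indices
  pt <- if (nrow(trials)) prepare_trials(trials)
  na <- length(spec$alpha_names)
  ai <- seq_len(na)
  wi <- if (spec$has_w) na + 1:2
  svi <- match(spec$sv_names, spec$par_names)
  sigi <- length(kinds)
  log_lik <- function(theta) {
    if (is.null(pt)) return(0)
    sum(.loglik_draws_cpp(pt$cell, pt$trials$feedback, pt$trials$expectation,
                          spec$amap, spec$svmap, spec$cell_session,
                          matrix(theta[ai], 1L),
                          matrix(if (spec$has_w) theta[wi] else c(0, 0), 1L),
                          matrix(theta[svi], 1L), theta[sigi],
                          config$sigma_nd, spec$mean_model))
  }
  log_post <- function(z) {
    ll <- log_lik(to_natural(z, kinds))
    if (!is.finite(ll)) return(-Inf)
    ll + log_prior_jac(z, kinds, config$prior_sigma_scale)
  }

  if (config$sampler == "mcmc") {
    res <- sample_mcmc(log_post, spec, kinds, config)
  } else {
    res <- sample_map(log_post, spec, kinds, config)
  }
  draws <- res$draws # kept x d, natural scale
  colnames(draws) <- spec$par_names

  summ <- tibble::tibble(
    parameter = spec$par_names,
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    rhat = res$rhat,
    n_eff = res$n_eff
  )
  if (any(is.finite(summ$rhat) & summ$rhat > config$rhat_max))
    flags <- c(flags, "non_convergence")

  ll <- if (nrow(trials)) loglik_matrix(spec, draws, trials, config$sigma_nd)
        else list(loglik = matrix(0, nrow(draws), 0L), trials = trials)

  structure(list(
    model = spec$id, spec = spec,
    participant = if (nrow(trials)) trials$participant[1] else NA,
    config = config, draws = draws, summary = summ,
    loglik = ll$loglik, trials = ll$trials,
    estimates = setNames(summ$mean, summ$parameter),
    map = res$map, flags = flags, accept_rate = res$accept_rate
  ), class = "loop_fit")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat(sprintf("<loop_fit %s, participant %s> %d draws, %d trials%s\n",
              x$model, format(x$participant), nrow(x$draws), nrow(x$trials),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# Posterior mode and Laplace curvature on the unconstrained scale, shared by
# both backends: the MAP sampler draws from it, the MCMC sampler starts its
# chains there with the curvature as initial proposal covariance.
map_mode <- function(log_post, spec, kinds, config) {
  d <- length(kinds)
  best <- NULL
  set.seed(sub_seed(config$seed, paste0("map", spec$id)))
  inits <- replicate(config$n_starts,
                     to_unconstrained(draw_init(spec, kinds,
                                                config$prior_sigma_scale),
                                      kinds),
                     simplify = FALSE)
  for (z0 in inits) {
    if (!is.finite(log_post(z0))) next
    opt <- try(optim(z0, function(z) -log_post(z), method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("MAP optimisation failed from all starts", call. = FALSE)
  hess <- try(stats::optimHess(best$par, function(z) -log_post(z)),
              silent = TRUE)
  Sigma <- NULL
  if (!inherits(hess, "try-error")) {
    Sigma <- try(solve((hess + t(hess)) / 2 + diag(1e-6, d)), silent = TRUE)
    if (inherits(Sigma, "try-error") ||
        any(!is.finite(Sigma)) || any(diag(Sigma) <= 0)) Sigma <- NULL
  }
  if (is.null(Sigma)) Sigma <- diag(0.01, d)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev$values <- pmin(pmax(ev$values, 1e-8), 25)
  Sigma <- ev$vectors %*% diag(ev$values, d) %*% t(ev$vectors)
  list(par = best$par, Sigma = Sigma)
}

# Adaptive random-walk Metropolis. Chains start at the posterior mode
# (jittered); the proposal keeps the Laplace curvature as its shape (scaled
# 2.38^2/d) and a scalar step size tunes toward 0.234 acceptance during
# burn-in, frozen afterwards. Tuning only the scalar keeps the adaptation
# stable where a full empirical-covariance update would collapse the steps.
sample_mcmc <- function(log_post, spec, kinds, config) {
  d <- length(kinds)
  kept_per_chain <- config$n_kept %/% config$n_chains
  n_post <- kept_per_chain * config$thin
  # chain initialisation needs a good mode, not the best of many: two
  # optimiser restarts are enough here (the MAP backend keeps all of them)
  cfg_init <- config
  cfg_init$n_starts <- min(config$n_starts, 2L)
  mode <- map_mode(log_post, spec, kinds, cfg_init)
  chol_mode <- chol(2.38^2 / d * mode$Sigma + diag(1e-8, d))
  chains <- vector("list", config$n_chains)
  accepts <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(sub_seed(config$seed, paste0("chain", ch, spec$id)))
    z <- mode$par + 0.3 * drop(rnorm(d) %*% chol_mode)
    lp <- log_post(z)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      z <- mode$par + 0.1 * drop(rnorm(d) %*% chol_mode)
      lp <- log_post(z)
      tries <- tries + 1
    }
    if (!is.finite(lp)) { z <- mode$par; lp <- log_post(z) }
    step <- 1
    kept <- matrix(NA_real_, kept_per_chain, d)
    n_acc <- 0; ki <- 0; acc_batch <- 0
    for (it in seq_len(config$n_burnin + n_post)) {
      zp <- z + step * drop(rnorm(d) %*% chol_mode)
      lpp <- log_post(zp)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        z <- zp; lp <- lpp; n_acc <- n_acc + 1; acc_batch <- acc_batch + 1
      }
      if (it <= config$n_burnin && it %% 50 == 0) {
        rate <- acc_batch / 50
        if (rate > 0.3) step <- step * 1.2
        if (rate < 0.15) step <- step / 1.2
        acc_batch <- 0
      }
      if (it > config$n_burnin &&
          (it - config$n_burnin) %% config$thin == 0) {
        ki <- ki + 1
        kept[ki, ] <- z
      }
    }
    chains[[ch]] <- kept
    accepts[ch] <- n_acc / (config$n_burnin + n_post)
  }
  draws_nat <- do.call(rbind, lapply(chains, function(m) {
    t(apply(m, 1, to_natural, kinds = kinds))
  }))
  diag_res <- chain_diagnostics(chains, kinds)
  list(draws = draws_nat, rhat = diag_res$rhat, n_eff = diag_res$n_eff,
       map = setNames(to_natural(mode$par, kinds), names(kinds)),
       accept_rate = mean(accepts))
}

# Split-R-hat (each chain halved) via coda's PSRF, and effective sample size,
# both on the natural scale.
chain_diagnostics <- function(chains, kinds) {
  d <- length(kinds)
  n <- nrow(chains[[1]])
  if (n < 4L) return(list(rhat = rep(NA_real_, d), n_eff = rep(NA_real_, d)))
  half <- n %/% 2L
  nat <- lapply(chains, function(m) t(apply(m, 1, to_natural, kinds = kinds)))
  splits <- unlist(lapply(nat, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  rhat <- vapply(seq_len(d), function(j) {
    ml <- coda::mcmc.list(lapply(splits, function(m) coda::mcmc(m[, j])))
    if (any(!is.finite(unlist(lapply(splits, function(m) m[, j]))))) return(NA_real_)
    v <- vapply(splits, function(m) var(m[, j]), 0)
    if (all(v < 1e-12)) return(1)
    out <- try(coda::gelman.diag(ml, autoburnin = FALSE,
                                 multivariate = FALSE)$psrf[1, 1],
               silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, 0)
  n_eff <- vapply(seq_len(d), function(j) {
    sum(vapply(nat, function(m) unname(coda::effectiveSize(m[, j])), 0))
  }, 0)
  list(rhat = rhat, n_eff = n_eff)
}

# Posterior mode by multi-start quasi-Newton optimisation, with draws from
# the Laplace (multivariate normal) approximation at the mode. Deterministic
# given the seed; no MCMC diagnostics apply.
sample_map <- function(log_post, spec, kinds, config) {
  d <- length(kinds)
  mode <- map_mode(log_post, spec, kinds, config)
  set.seed(sub_seed(config$seed, paste0("laplace", spec$id)))
  zd <- mvtnorm::rmvnorm(config$n_kept, mean = mode$par, sigma = mode$Sigma)
  draws <- t(apply(zd, 1, to_natural, kinds = kinds))
  list(draws = draws, rhat = rep(NA_real_, d), n_eff = rep(NA_real_, d),
       map = setNames(to_natural(mode$par, kinds), names(kinds)),
       accept_rate = NA_real_)
}

#' Fit several participants under several models
#'
#' @param trials Trial tibble for a cohort.
#' @param models Character vector of model ids.
#' @param config A [fit_config()]; each participant-model fit derives its own
#'   seed substream from `config$seed`.
#' @param slim If `TRUE`, PSIS-LOO evidence is computed eagerly per fit
#'   (columns `elpd`, `elpd_T1`, `elpd_T2`, `frac_khat_high`) and the stored
#'   fits are stripped of their draw and log-likelihood matrices, keeping
#'   memory flat for large cohorts.
#' @return A tibble with one row per participant and model and a `fit`
#'   list-column of `loop_fit` objects.
#' @export
fit_cohort <- function(trials, models = model_ids(), config = fit_config(),
                       slim = FALSE) {
  parts <- sort(unique(trials$participant))
  out <- tidyr::expand_grid(participant = parts, model = models) |>
    dplyr::mutate(fit = purrr::map2(.data$participant, .data$model, function(p, m) {
      cfg <- config
      cfg$seed <- sub_seed(config$seed, paste0("fit", p, m))
      fit_participant(m, dplyr::filter(trials, .data$participant == p), cfg)
    }))
  if (!slim) return(out)
  # smoothing is independent across trials, so session sums come from one pass
  loos <- purrr::map(out$fit, psis_loo)
  out$elpd <- purrr::map_dbl(loos, "elpd")
  out$elpd_T1 <- purrr::map_dbl(loos, function(l)
    sum(l$pointwise$elpd[l$pointwise$session == "T1"]))
  out$elpd_T2 <- purrr::map_dbl(loos, function(l)
    sum(l$pointwise$elpd[l$pointwise$session == "T2"]))
  out$frac_khat_high <- purrr::map_dbl(loos, "frac_khat_high")
  out$fit <- purrr::map(out$fit, function(f) {
    f$draws <- NULL
    f$loglik <- NULL
    f$slim <- TRUE
    f
  })
  out
}

#' Posterior predictive trajectories for a fitted participant
#'
#' Predicts the expectation time course per cell from the posterior-mean
#' parameters, paired with the observed ratings, for overlay plots and a
#' per-participant variance-explained summary.
#'
#' @param fit A `loop_fit`.
#' @return A tibble with `session`, `agent`, `ability`, `category`, `trial`,
#'   `observed` and `predicted`; attribute `r_squared` holds the proportion
#'   of rating variance captured.
#' @export
posterior_predictive <- function(fit) {
  stopifnot(inherits(fit, "loop_fit"))
  pred <- predict_expectations(fit$spec, fit$estimates, fit$trials,
                               fit$config$sigma_nd)
  out <- dplyr::mutate(
    dplyr::select(fit$trials, dplyr::any_of(c("participant", "session",
      "agent", "ability", "category", "trial", "expectation"))),
    observed = .data$expectation, predicted = pred) |>
    dplyr::select(-"expectation")
  ss_res <- sum((out$observed - out$predicted)^2)
  ss_tot <- sum((out$observed - mean(out$observed))^2)
  attr(out, "r_squared") <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out
}
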