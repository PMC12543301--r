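# Smaller-than-default sampling schemes are used throughout to keep the
# suite quick; draw-count bookkeeping itself is asserted exactly.

quick_cfg <- function(seed = 1, ...) {
  fit_config(n_chains = 2L, n_burnin = 200L, n_kept = 300L, thin = 2L,
             seed = seed, ...)
}

test_that("draw-count bookkeeping matches the configuration exactly", {
  tr <- small_trials("M1", seed = 3)
  f <- fit_participant("M1", tr, quick_cfg(seed = 5))
  expect_identical(nrow(f$draws), 300L)
  expect_identical(dim(f$loglik), c(300L, nrow(tr)))
  f_default <- fit_config()
  expect_identical(f_default$n_kept, 2400L)
  expect_identical(f_default$n_burnin, 1000L)
  expect_identical(f_default$n_chains, 3L)
  expect_identical(f_default$thin, 3L)
  # per-chain total iterations = burn-in + kept/chains * thin = 3400
  expect_identical(f_default$n_burnin +
                     f_default$n_kept %/% f_default$n_chains * f_default$thin,
                   3400L)
  expect_error(fit_config(n_chains = 3, n_kept = 1000), "n_kept")
})

test_that("fits are reproducible from the seed for both samplers", {
  tr <- small_trials("M1", seed = 7)
  for (smp in c("mcmc", "map")) {
    f1 <- fit_participant("M1", tr, quick_cfg(seed = 11, sampler = smp))
    f2 <- fit_participant("M1", tr, quick_cfg(seed = 11, sampler = smp))
    expect_identical(f1$summary, f2$summary, info = smp)
    expect_identical(f1$draws, f2$draws, info = smp)
  }
})

test_that("with no data the posterior reproduces the prior", {
  tr0 <- small_trials("M1", seed = 13)[0, ]
  f <- fit_participant("M1", tr0, fit_config(n_chains = 2, n_burnin = 500,
                                             n_kept = 2000, thin = 2,
                                             seed = 17))
  est <- f$estimates
  expect_lt(abs(est[["alpha_Self"]] - 0.5), 0.08)
  expect_lt(abs(est[["sv_T1_Self_High"]] - 50), 8)
})

test_that("posterior means of bounded parameters respect their bounds", {
  tr <- small_trials("M7", seed = 19)
  f <- fit_participant("M7", tr, quick_cfg(seed = 23, sampler = "map"))
  est <- f$estimates
  a <- est[grep("^alpha|^w_", names(est))]
  expect_true(all(a >= 0 & a <= 1))
  sv <- est[grep("^sv_", names(est))]
  expect_true(all(sv >= 0 & sv <= 100))
  expect_gt(est[["sigma"]], 0)
})

test_that("parameters generating the data are recovered on synthetic trials", {
  spec <- model_spec("M1")
  d <- make_design(1, seed = 29)
  pars <- setNames(c(0.3, 0.2, rep(c(40, 60), 4), 5), spec$par_names)
  tr <- simulate_trajectory(spec, pars, d, noise = TRUE, seed = 31)
  expect_equal(nrow(tr), 160)
  f_map <- fit_participant("M1", tr, quick_cfg(seed = 37, sampler = "map"))
  expect_lt(abs(f_map$map[["alpha_Self"]] - 0.3), 0.08)
  expect_lt(abs(f_map$map[["alpha_Other"]] - 0.2), 0.08)
  # interval calibration: across independent datasets the 95% posterior
  # interval should cover the generating rate in (at least) most of them
  covered <- 0
  for (k in 1:4) {
    trk <- simulate_trajectory(spec, pars, d, noise = TRUE, seed = 300 + k)
    fk <- fit_participant("M1", trk, fit_config(seed = 40 + k))
    ci <- quantile(fk$draws[, "alpha_Self"], c(0.025, 0.975))
    covered <- covered + (ci[[1]] <= 0.3 && 0.3 <= ci[[2]])
    if (k == 1) {
      expect_true(all(is.finite(fk$summary$rhat)))
      expect_true(all(fk$summary$n_eff > 0))
    }
  }
  expect_gte(covered, 3)
})

test_that("degenerate and partial data are flagged, never silently accepted", {
  tr <- small_trials("M1", seed = 43)
  flat <- dplyr::mutate(tr, expectation = 50)
  f <- fit_participant("M1", flat, quick_cfg(seed = 47, sampler = "map"))
  expect_true("degenerate_constant_ratings" %in% f$flags)
  one_session <- dplyr::filter(tr, session == "T1")
  f1 <- fit_participant("M1", one_session, quick_cfg(seed = 53, sampler = "map"))
  expect_true("single_session" %in% f1$flags)
})

test_that("posterior predictions overlay noise-free data and start at the fitted SVs", {
  spec <- model_spec("M1")
  d <- make_design(1, seed = 59)
  pars <- setNames(c(0.35, 0.15, rep(c(45, 55), 4), 2), spec$par_names)
  tr <- simulate_trajectory(spec, pars, d, noise = FALSE)
  f <- fit_participant("M1", tr, quick_cfg(seed = 61, sampler = "map"))
  pp <- posterior_predictive(f)
  expect_gt(attr(pp, "r_squared"), 0.99)
  first <- dplyr::filter(pp, trial == 1)
  sv_fit <- f$estimates[paste("sv", first$session, first$agent, first$ability,
                              sep = "_")]
  expect_equal(first$predicted, unname(sv_fit), tolerance = 1e-9)
  # exact overlay when predicting from the generating parameters themselves
  expect_equal(predict_expectations(spec, pars, tr), tr$expectation,
               tolerance = 1e-9)
})

test_that("slim cohort fits carry session-additive LOO evidence without heavy matrices", {
  co <- sample_cohort(cohort_config(n_participants = 2, seed = 67))
  fits <- fit_cohort(co$trials, c("M1", "M9"), quick_cfg(seed = 71, sampler = "map"),
                     slim = TRUE)
  expect_true(all(c("elpd", "elpd_T1", "elpd_T2") %in% names(fits)))
  expect_equal(fits$elpd, fits$elpd_T1 + fits$elpd_T2, tolerance = 1e-9)
  expect_null(fits$fit[[1]]$loglik)
  expect_error(psis_loo(fits$fit[[1]]), "slim")
  ev <- loo_evidence(fits, session = "T1")
  expect_identical(dim(ev), c(2L, 2L))
})
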