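test_that("normal-density weighting peaks at 50, is symmetric, and matches the closed form", {
  expect_equal(nd_weight(50, 3), 1)
  expect_equal(nd_weight(50, 40), 1)
  expect_equal(nd_weight(0, 17), nd_weight(100, 17))
  expect_equal(nd_weight(67, 17), exp(-0.5))
  fb <- seq(0, 48, by = 4)
  expect_true(all(diff(nd_weight(fb, 17)) > 0)) # rising toward the centre
  expect_error(nd_weight(50, 0), "sigma_nd")
})

test_that("congruency follows the majority valence of the session-current ability", {
  expect_equal(congruency("High", "+"), "congruent")
  expect_equal(congruency("Low", "+"), "incongruent")
  expect_equal(congruency("High", "-"), "incongruent")
  expect_equal(congruency("Low", "-"), "congruent")
  expect_equal(congruency("Low", 12.5), "incongruent") # numeric PE
  # a former-High category is Low at T2, so a positive PE there is incongruent
  t1 <- dplyr::filter(make_design(1, seed = 1), session == "T1",
                      ability == "High")
  t2_ability <- unique(reverse_contingencies(t1)$ability)
  expect_equal(congruency(t2_ability, "+"), "incongruent")
})

test_that("the registry partitions learning rates as each model demands", {
  n_alpha <- c(M1 = 2, M2 = 4, M3 = 4, M4 = 4, M5 = 8, M6 = 8, M7 = 8,
               M8 = 8, M9 = 0)
  n_par <- c(M1 = 11, M2 = 13, M3 = 13, M4 = 13, M5 = 17, M6 = 17, M7 = 19,
             M8 = 17, M9 = 9)
  for (id in names(n_alpha)) {
    spec <- model_spec(id)
    expect_length(spec$alpha_names, n_alpha[[id]])
    expect_length(spec$par_names, n_par[[id]])
    expect_equal(spec$has_w, id == "M7")
  }
  expect_error(model_spec("M10"), "unknown model")
})

test_that("the update rule matches its closed form and discounting shuts learning down", {
  expect_equal(update_expectation(50, 70, 0.5), 60)
  # with the density peak at the feedback value, w = 1 cancels the update
  expect_equal(update_expectation(50, 70, 0.5, w = 1, sigma_nd = 1e9), 50,
               tolerance = 1e-9)
  expect_equal(update_expectation(40, 90, 0.8, w = 0.5, sigma_nd = 17),
               oracle_update(40, 90, 0.8, 0.5, 17))
  set.seed(31)
  for (i in 1:200) {
    e <- runif(1, 0, 100); f <- runif(1, 0, 100)
    u <- update_expectation(e, f, runif(1), runif(1), runif(1, 5, 40))
    expect_gte(u, min(e, f) - 1e-12)
    expect_lte(u, max(e, f) + 1e-12)
  }
})

test_that("every model's predictions match the independent scalar oracle", {
  tr <- small_trials("M3", seed = 7)
  for (id in paste0("M", 1:9)) {
    spec <- model_spec(id)
    set.seed(match(id, paste0("M", 1:9)) + 100)
    pars <- random_params(spec)
    expect_equal(predict_expectations(spec, pars, tr),
                 oracle_predict_trials(id, pars, tr),
                 tolerance = 1e-12, info = id)
  }
})

test_that("pointwise log-likelihood matches a scalar brute-force evaluation on a 5-trial fixture", {
  tr <- tibble::tibble(
    participant = 1, session = "T1", agent = "Self", ability = "High",
    category = "heights", trial = 1:5,
    expectation = c(42, 55, 61, 58, 70),
    feedback = c(60, 72, 55, 80, 77)
  )
  spec <- model_spec("M3")
  set.seed(5)
  pars <- random_params(spec, sigma = 9)
  ll <- pointwise_loglik(spec, pars, tr)
  # oracle: sequential scalar updates and truncated-normal scoring
  sv <- unname(pars["sv_T1_Self_High"])
  pred <- numeric(5); cur <- sv
  for (t in 1:5) {
    pred[t] <- cur
    pe <- tr$feedback[t] - cur
    a <- unname(pars[if (pe > 0) "alpha_Self_pos" else "alpha_Self_neg"])
    cur <- cur + a * pe
  }
  expect_equal(ll, oracle_lp(tr$expectation, pred, 9), tolerance = 1e-12)
  expect_equal(sum(ll), sum(oracle_lp(tr$expectation, pred, 9)),
               tolerance = 1e-12)
  # first trial is scored against the starting value
  expect_equal(pred[1], sv)
})

test_that("likelihood peaks when observations equal predictions and flattens as sigma grows", {
  tr <- small_trials("M1", seed = 9)
  spec <- model_spec("M1")
  set.seed(11)
  pars <- random_params(spec, sigma = 10)
  pred <- predict_expectations(spec, pars, tr)
  tr_perfect <- dplyr::mutate(tr, expectation = pmin(100, pmax(0, pred)))
  ll10 <- pointwise_loglik(spec, pars, tr_perfect)
  pars20 <- pars; pars20["sigma"] <- 20
  expect_gt(sum(ll10), sum(pointwise_loglik(spec, pars20, tr_perfect)))
  expect_error(pointwise_loglik(spec, replace(pars, "sigma", -1), tr), "sigma")
})

test_that("the model-nesting chain M7 -> M6 -> M3 -> M1 holds to machine precision", {
  tr <- small_trials("M7", seed = 13)
  s7 <- model_spec("M7"); s6 <- model_spec("M6")
  s3 <- model_spec("M3"); s1 <- model_spec("M1")
  set.seed(17)
  p6 <- random_params(s6)
  p7 <- c(p6[s6$alpha_names], w_T1 = 0, w_T2 = 0, p6[s6$sv_names],
          sigma = unname(p6["sigma"]))
  names(p7) <- c(s6$alpha_names, "w_T1", "w_T2", s6$sv_names, "sigma")
  expect_equal(pointwise_loglik(s7, p7[s7$par_names], tr),
               pointwise_loglik(s6, p6, tr), tolerance = 1e-15)

  p3 <- random_params(s3)
  p6c <- setNames(c(p3[paste0("alpha_", c("Self_pos", "Self_neg",
                                          "Other_pos", "Other_neg"))],
                    p3[paste0("alpha_", c("Self_pos", "Self_neg",
                                          "Other_pos", "Other_neg"))],
                    p3[s3$sv_names], p3["sigma"]), s6$par_names)
  expect_equal(pointwise_loglik(s6, p6c, tr),
               pointwise_loglik(s3, p3, tr), tolerance = 1e-15)

  p1 <- random_params(s1)
  p3c <- setNames(c(rep(p1[c("alpha_Self", "alpha_Other")], each = 2),
                    p1[s1$sv_names], p1["sigma"]), s3$par_names)
  expect_equal(pointwise_loglik(s3, p3c, tr),
               pointwise_loglik(s1, p1, tr), tolerance = 1e-15)

  # trajectory equality under the same noise stream
  d <- make_design(1, seed = 19)
  t7 <- simulate_trajectory(s7, p7[s7$par_names], d, noise = TRUE, seed = 23)
  t6 <- simulate_trajectory(s6, p6, d, noise = TRUE, seed = 23)
  expect_identical(t7, t6)
})

test_that("mean-model likelihood is invariant to trial order within a cell", {
  tr <- small_trials("M9", seed = 29)
  spec <- model_spec("M9")
  set.seed(30)
  pars <- random_params(spec)
  ll <- sum(pointwise_loglik(spec, pars, tr))
  set.seed(33)
  shuf <- tr |>
    dplyr::group_by(session, agent, ability) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::ungroup()
  expect_equal(sum(pointwise_loglik(spec, pars, shuf)), ll, tolerance = 1e-12)
})

test_that("simulated trajectories obey the no-learning and full-updating limits", {
  d <- make_design(1, seed = 35)
  s1 <- model_spec("M1")
  p0 <- setNames(c(0, 0, rep(c(35, 65), 4), 5), s1$par_names)
  t0 <- simulate_trajectory(s1, p0, d, noise = FALSE)
  sv_of <- function(tr) unname(p0[paste("sv", tr$session, tr$agent,
                                        tr$ability, sep = "_")])
  expect_equal(t0$expectation, sv_of(t0)) # flat at SV without learning
  p1 <- setNames(c(1, 1, rep(50, 8), 5), s1$par_names)
  t1 <- simulate_trajectory(s1, p1, d, noise = FALSE)
  one_cell <- dplyr::filter(t1, session == "T1", agent == "Self",
                            ability == "High") |> dplyr::arrange(trial)
  expect_equal(one_cell$expectation[-1],
               one_cell$feedback[-nrow(one_cell)]) # EXP_{t+1} = FB_t
})
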