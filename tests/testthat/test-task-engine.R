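test_that("feedback plans carry the 70/30 valence split, 20 trials per cell, no zero modifiers", {
  d <- make_design(3, seed = 2)
  counts <- dplyr::count(d, participant, session, agent, ability, category)
  expect_true(all(counts$n == 20))
  pos <- d |>
    dplyr::group_by(participant, session, agent, ability, category) |>
    dplyr::summarise(n_pos = sum(modifier > 0), .groups = "drop")
  expect_true(all(pos$n_pos[pos$ability == "High"] == 14))
  expect_true(all(pos$n_pos[pos$ability == "Low"] == 6))
  expect_true(all(d$modifier != 0))
})

test_that("category-cell assignment is counterbalanced and stable across sessions", {
  d <- make_design(8, seed = 1)
  t1 <- dplyr::distinct(dplyr::filter(d, session == "T1"),
                        participant, agent, ability, category)
  per_cell <- dplyr::count(t1, agent, ability, category)
  expect_true(all(per_cell$n == 2)) # 8 participants / 4 rotations
  # same category-agent pairing at T2, ability flipped
  t2 <- dplyr::distinct(dplyr::filter(d, session == "T2"),
                        participant, agent, ability, category)
  j <- dplyr::inner_join(t1, t2, by = c("participant", "category"),
                         suffix = c("_1", "_2"))
  expect_equal(j$agent_1, j$agent_2)
  expect_true(all(j$ability_1 != j$ability_2))
})

test_that("designs are byte-identical given the same seed", {
  expect_identical(make_design(5, seed = 9), make_design(5, seed = 9))
  expect_false(identical(make_design(5, seed = 9), make_design(5, seed = 10)))
})

test_that("reference belief is 50 when empty and the mean of the last five otherwise", {
  expect_equal(reference_belief(numeric(0)), 50)
  expect_equal(reference_belief(c(60, 70, 80, 90, 100)), 80)
  expect_equal(reference_belief(c(10, 60, 70, 80, 90, 100)), 80)
  expect_equal(reference_belief(c(40, 60)), 50)
  expect_error(reference_belief(c(50, 120)), "out of")
})

test_that("feedback adds the modifier and clips to the percentile scale", {
  expect_equal(compute_feedback(50, 20), 70)
  expect_equal(compute_feedback(95, 20), 100)
  expect_equal(compute_feedback(80, -15), 65)
  expect_equal(compute_feedback(5, -20), 0)
})

test_that("contingency reversal flips valence, preserves magnitudes, and is an involution", {
  d1 <- dplyr::filter(make_design(2, seed = 3), session == "T1")
  d2 <- reverse_contingencies(d1)
  expect_true(all(d2$session == "T2"))
  pos2 <- d2 |>
    dplyr::group_by(participant, category, ability) |>
    dplyr::summarise(n_pos = sum(modifier > 0), .groups = "drop")
  expect_true(all(pos2$n_pos[pos2$ability == "High"] == 14))
  expect_true(all(pos2$n_pos[pos2$ability == "Low"] == 6))
  for (p in unique(d1$participant)) {
    for (cc in unique(d1$category)) {
      m1 <- sort(abs(d1$modifier[d1$participant == p & d1$category == cc]))
      m2 <- sort(abs(d2$modifier[d2$participant == p & d2$category == cc]))
      expect_identical(m1, m2)
    }
  }
  expect_identical(reverse_contingencies(d2), d1)
})

test_that("run_session closes the adaptive loop around the agent's ratings", {
  plan <- dplyr::filter(make_design(1, seed = 4), session == "T1")
  rec <- run_session(plan, function(cat, t, eh, fh) 50)
  # constant-50 agent keeps the trailing mean at 50, so PE tracks the modifier
  expect_equal(rec$pe, rec$modifier)
  expect_equal(rec$feedback, 50 + rec$modifier)
  expect_equal(rec$pe, rec$feedback - rec$expectation)

  plan10 <- dplyr::mutate(plan, modifier = 10)
  rec10 <- run_session(plan10, function(cat, t, eh, fh) 50)
  expect_true(all(rec10$feedback == 60))
  expect_true(all(rec10$pe == 10))

  expect_error(run_session(plan, function(cat, t, eh, fh) 130), "out of")
})

test_that("an agent echoing the previous feedback matches a brute-force trajectory oracle", {
  plan <- dplyr::filter(make_design(1, seed = 6), session == "T1")
  echo <- function(cat, t, eh, fh) if (length(fh)) fh[length(fh)] else 50
  rec <- run_session(plan, echo)
  # oracle: straightforward per-category loop over presentation order
  plan_o <- dplyr::arrange(plan, trial, category)
  exp_o <- fb_o <- numeric(nrow(plan_o))
  cats <- unique(plan_o$category)
  hist_e <- hist_f <- setNames(vector("list", length(cats)), cats)
  for (i in seq_len(nrow(plan_o))) {
    k <- plan_o$category[i]
    eh <- unlist(hist_e[[k]]); fh <- unlist(hist_f[[k]])
    exp_o[i] <- if (length(fh)) fh[length(fh)] else 50
    ref <- if (length(eh)) mean(tail(eh, 5)) else 50
    fb_o[i] <- min(100, max(0, ref + plan_o$modifier[i]))
    hist_e[[k]] <- c(hist_e[[k]], exp_o[i])
    hist_f[[k]] <- c(hist_f[[k]], fb_o[i])
  }
  expect_equal(rec$expectation, exp_o)
  expect_equal(rec$feedback, fb_o)
})

test_that("PE valence matches the plan and |PE| is preserved across the reversal for a reference-tracking agent", {
  d <- make_design(1, seed = 8)
  ref_agent <- function(cat, t, eh, fh) if (length(eh)) mean(tail(eh, 5)) else 50
  rec1 <- run_session(dplyr::filter(d, session == "T1"), ref_agent)
  rec2 <- run_session(dplyr::filter(d, session == "T2"), ref_agent)
  # rating equals the reference, so PE equals the modifier exactly
  expect_equal(rec1$pe, rec1$modifier)
  expect_equal(rec2$pe, rec2$modifier)
  for (cc in unique(rec1$category)) {
    expect_identical(sort(abs(rec1$pe[rec1$category == cc])),
                     sort(abs(rec2$pe[rec2$category == cc])))
  }
  high1 <- rec1$ability == "High"
  expect_gte(mean(rec1$pe[high1] > 0), 0.5)
  expect_true(all(rec1$feedback >= 0 & rec1$feedback <= 100))
  expect_true(all(abs(rec1$pe) <= 100))
})

test_that("accuracy incentive peaks at 6 cents and decays linearly to zero", {
  expect_equal(trial_incentive(70, 70), 6)
  expect_equal(trial_incentive(40, 90), 6 * 0.5)
  expect_equal(trial_incentive(0, 100), 0)
  grid <- expand.grid(e = seq(0, 100, 10), f = seq(0, 100, 10))
  expect_equal(max(trial_incentive(grid$e, grid$f)), 6)
})
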