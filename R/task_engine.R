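# Task engine: session designs and adaptive percentile feedback.
#
# The task manipulates performance feedback in four estimation categories
# crossed over agent (Self / Other) and ability (High / Low). Feedback on each
# trial equals the participant's trailing belief (mean of the last five
# expectation ratings in that category, 50 before the first) plus a signed
# modifier; High-ability cells carry 70% positive modifiers, Low cells 30%.
# At the second session the contingencies reverse: each category keeps its
# modifier magnitudes but flips their signs, so prediction errors match in
# absolute size and differ only in valence.

LOOP_CATEGORIES <- c("heights", "weights", "quantities", "distances")
LOOP_AGENTS     <- c("Self", "Other")
LOOP_ABILITIES  <- c("High", "Low")
LOOP_SESSIONS   <- c("T1", "T2")

# Canonical cell table: 4 agent x ability cells in fixed order.
loop_cells <- function() {
  tibble::tibble(
    agent   = rep(LOOP_AGENTS, each = 2L),
    ability = rep(LOOP_ABILITIES, times = 2L)
  )
}

#' Build counterbalanced session designs with adaptive-feedback plans
#'
#' Assigns the four estimation categories to the four agent-by-ability cells
#' using rotations cycled across participants (so with `n_participants` a
#' multiple of 4 every category serves in every cell equally often), and draws
#' a 20-trial feedback plan per cell and session. High-ability cells receive
#' 14 positive and 6 negative modifiers (70% / 30%), Low cells the reverse.
#' Session T2 plans are the sign-flipped T1 plans of the same category, while
#' the category's ability label flips, implementing the contingency reversal.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the design is fully reproducible from it.
#' @param n_trials Trials per cell and session (default 20).
#' @param modifier_magnitudes Multiset of absolute modifier values cycled to
#'   fill each cell's plan (percentile units, all > 0).
#' @param constrain_start If `TRUE` (default), the first two trials of a cell
#'   are never both incongruent with the cell's majority valence.
#' @return A tibble with one row per participant, session, category and trial:
#'   `participant`, `session`, `agent`, `ability`, `category`, `trial`,
#'   `modifier`.
#' @export
#' @examples
#' d <- make_design(2, seed = 1)
#' dplyr::count(d, session, ability, positive = modifier > 0)
make_design <- function(n_participants, seed,
                        n_trials = 20L,
                        modifier_magnitudes = c(5, 8, 11, 14, 17, 20, 23, 26),
                        constrain_start = TRUE) {
  stopifnot(n_participants >= 1, n_trials >= 1, all(modifier_magnitudes > 0))
  rng <- sub_seed(seed, "design")
  purrr::map_dfr(seq_len(n_participants), function(p) {
    rot <- (p - 1L) %% 4L
    cells <- loop_cells()
    cells$category <- LOOP_CATEGORIES[((seq_len(4L) - 1L + rot) %% 4L) + 1L]
    t1 <- purrr::map_dfr(seq_len(4L), function(i) {
      cell_seed <- sub_seed(rng, paste("cell", p, cells$category[i]))
      mods <- feedback_plan(cells$ability[i], n_trials, modifier_magnitudes,
                            cell_seed, constrain_start)
      tibble::tibble(
        participant = p, session = "T1",
        agent = cells$agent[i], ability = cells$ability[i],
        category = cells$category[i],
        trial = seq_len(n_trials), modifier = mods
      )
    })
    dplyr::bind_rows(t1, reverse_contingencies(t1))
  })
}

# One cell's ordered modifier sequence for a session.
feedback_plan <- function(ability, n_trials, magnitudes, seed, constrain_start) {
  set.seed(seed)
  m <- sample(rep(magnitudes, length.out = n_trials))
  majority_pos <- ability == "High"
  n_major <- round(0.7 * n_trials)
  repeat {
    major_at <- sort(sample(n_trials, n_major))
    if (!constrain_start || any(c(1L, 2L) %in% major_at)) break
  }
  signs <- rep(if (majority_pos) -1 else 1, n_trials)
  signs[major_at] <- if (majority_pos) 1 else -1
  m * signs
}

#' Trailing reference belief used to anchor feedback
#'
#' The feedback algorithm anchors each trial's feedback on the participant's
#' current belief: the mean of the last five expectation ratings in the
#' category, or 50 before any rating exists.
#'
#' @param history Numeric vector of previous expectation ratings (possibly
#'   empty), each in `[0, 100]`.
#' @return The reference percentile.
#' @export
#' @examples
#' reference_belief(numeric(0)) # 50
#' reference_belief(c(60, 70, 80, 90, 100)) # 80
reference_belief <- function(history) {
  if (length(history) == 0L) return(50)
  assert_rating(history, "expectation history")
  mean(tail(history, 5L))
}

#' Compute one trial's feedback percentile
#'
#' Feedback is the trailing reference belief plus the trial's signed modifier,
#' clipped to the percentile scale (clip events can be counted from the
#' returned value hitting 0 or 100).
#'
#' @param reference Reference belief in `[0, 100]`.
#' @param modifier Signed modifier (percentile units).
#' @return Feedback percentile in `[0, 100]`.
#' @export
compute_feedback <- function(reference, modifier) {
  assert_rating(reference, "reference belief")
  clip01(reference + modifier)
}

#' Reverse feedback contingencies for the second session
#'
#' Flips each category's ability label and negates its modifier sequence, so
#' the T2 sign pattern equals that of the opposite ability level while the
#' multiset of absolute modifiers per category is preserved. Applying the
#' reversal twice returns the original plan.
#'
#' @param plan Design tibble for one session (as produced by [make_design()]).
#' @return The reversed plan with `session` advanced (`T1` -> `T2`, `T2` ->
#'   `T1`).
#' @export
reverse_contingencies <- function(plan) {
  dplyr::mutate(plan,
    session  = ifelse(.data$session == "T1", "T2", "T1"),
    ability  = ifelse(.data$ability == "High", "Low", "High"),
    modifier = -.data$modifier
  )
}

#' Run one session of the adaptive-feedback loop
#'
#' Plays a feedback plan against an agent: on every trial the agent produces
#' an expectation rating given its per-category history, feedback is computed
#' from the trailing reference belief plus the planned modifier, and the
#' prediction error `PE = FB - EXP` is recorded. Trials are presented
#' round-robin across categories in trial order.
#'
#' @param plan Design rows for one participant and session.
#' @param agent_behavior Function `(category, trial, exp_history, fb_history)`
#'   returning an expectation rating in `[0, 100]`; histories are the ratings
#'   and feedbacks already observed in that category.
#' @return A trial-record tibble: `participant`, `session`, `agent`,
#'   `ability`, `category`, `trial`, `expectation`, `feedback`, `pe`,
#'   `modifier`.
#' @export
#' @examples
#' plan <- dplyr::filter(make_design(1, seed = 1), session == "T1")
#' rec <- run_session(plan, function(cat, t, eh, fh) 50)
run_session <- function(plan, agent_behavior) {
  stopifnot(length(unique(plan$session)) == 1L)
  plan <- dplyr::arrange(plan, .data$trial, .data$category)
  cats <- unique(plan$category)
  exp_hist <- fb_hist <- setNames(rep(list(numeric(0)), length(cats)), cats)
  n <- nrow(plan)
  expectation <- feedback <- numeric(n)
  for (i in seq_len(n)) {
    cat_i <- plan$category[i]
    e <- agent_behavior(cat_i, plan$trial[i], exp_hist[[cat_i]], fb_hist[[cat_i]])
    assert_rating(e, "agent rating")
    # belief anchor predates the current rating: trial 1 anchors at 50
    ref <- reference_belief(exp_hist[[cat_i]])
    fb <- compute_feedback(ref, plan$modifier[i])
    expectation[i] <- e
    feedback[i] <- fb
    exp_hist[[cat_i]] <- c(exp_hist[[cat_i]], e)
    fb_hist[[cat_i]] <- c(fb_hist[[cat_i]], fb)
  }
  dplyr::mutate(plan, expectation = expectation, feedback = feedback,
                pe = feedback - expectation) |>
    dplyr::select("participant", "session", "agent", "ability", "category",
                  "trial", "expectation", "feedback", "pe", "modifier")
}

#' Per-trial accuracy incentive
#'
#' Accurate expectation ratings earn up to 6 cents per trial; the payout
#' decays linearly with the absolute gap between the rating and the feedback
#' percentile and is floored at zero.
#'
#' @param expectation,feedback Percentiles in `[0, 100]`.
#' @param max_cents Maximum payout at zero error (default 6).
#' @return Payout in cents.
#' @export
trial_incentive <- function(expectation, feedback, max_cents = 6) {
  assert_rating(expectation, "expectation")
  assert_rating(feedback, "feedback")
  pmax(0, max_cents * (1 - abs(feedback - expectation) / 100))
}
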