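# Synthetic cohorts with the statistical structure the analysis assumes:
# two sessions x two agents x two ability levels x 20 trials per participant,
# adaptive feedback, ratings generated from a chosen learning model with
# observation noise, plus configurable population effects (self-negativity
# bias, suppressed revision-phase learning, a correlation between starting
# values and valence bias, and confidence trajectories coupled to learning).

tnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clip01(mean, lo, hi), n))
  p_lo <- pnorm(lo, mean, sd); p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Configure a synthetic cohort
#'
#' Population parameters are drawn from truncated normals on their native
#' scales. The self-negativity bias enters as `delta_alpha_self =
#' alpha(self, PE-) - alpha(self, PE+)` at T1 (positive values produce a
#' negative valence-bias score); `t2_suppression` multiplies every T1
#' learning rate to give the T2 rates; `sv_bias_rho` is induced through a
#' shared latent standard-normal factor loading on both the self starting
#' values and the self bias; `conf_alpha_rho` couples the post-T1 confidence
#' level (negatively) to the T2 mean learning rate.
#'
#' @param n_participants Cohort size.
#' @param model Generating model id (default `"M7"`).
#' @param seed Master seed.
#' @param alpha_mean,alpha_sd Population mean / sd of the base T1 learning
#'   rate.
#' @param alpha_lo,alpha_hi Truncation bounds for learning rates.
#' @param alpha_dist `"tnorm"` (default) or `"unif"`; with `"unif"`, every
#'   learning-rate component is drawn independently and uniformly from
#'   `[alpha_lo, alpha_hi]` and the bias/suppression knobs are ignored.
#' @param delta_alpha_self,delta_alpha_other Mean valence asymmetry
#'   (`PE- minus PE+`) for self- and other-related rates at T1.
#' @param delta_sd Individual sd of the asymmetries.
#' @param t2_suppression Multiplier applied to T1 rates to give T2 rates.
#' @param sv_bias_rho Target correlation between self starting values and the
#'   self T1 valence-bias score.
#' @param w_mean,w_sd Population distribution of the discounting weight
#'   (extended valence model only).
#' @param sv_mean,sv_sd Population distribution of the T1 starting values.
#' @param sv_t2_shift Learned separation at T2: former-High cells start this
#'   much above the participant's central value, former-Low the same amount
#'   below.
#' @param sv_cell_sd Cell-level scatter of starting values around the
#'   participant's central value.
#' @param sigma Observation noise (percentile units).
#' @param conf_pre_t1,conf_gain_t1,conf_t2_decay,conf_sd Confidence
#'   trajectory: pre-T1 level, post-T1 gain, drop of the T2 levels, and
#'   rating noise.
#' @param conf_alpha_rho Coupling between post-T1 confidence and T2 learning
#'   (negative: confident participants revise less).
#' @return A `loop_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 30, model = "M7", seed = 1,
                          alpha_mean = 0.25, alpha_sd = 0.12,
                          alpha_lo = 0.02, alpha_hi = 0.9,
                          alpha_dist = c("tnorm", "unif"),
                          delta_alpha_self = 0.07, delta_alpha_other = -0.055,
                          delta_sd = 0.1, t2_suppression = 0.45,
                          sv_bias_rho = 0.3,
                          w_mean = 0.35, w_sd = 0.2,
                          sv_mean = 55, sv_sd = 12, sv_t2_shift = 14,
                          sv_cell_sd = 3, sigma = 8,
                          conf_pre_t1 = 55, conf_gain_t1 = 12,
                          conf_t2_decay = 4, conf_sd = 8,
                          conf_alpha_rho = -0.3) {
  alpha_dist <- match.arg(alpha_dist)
  if (abs(sv_bias_rho) > 0.9 && delta_sd > 0.15)
    warning("near-unit sv_bias_rho with high parameter variance is infeasible")
  cfg <- as.list(environment())
  structure(cfg, class = "loop_cohort_config")
}

#' Cohort preset mirroring the reference study's qualitative structure
#'
#' Two sessions of four 20-trial conditions for 99 participants generated
#' from the extended valence model, with a negative mean self valence bias
#' and positive other bias at T1, suppressed T2 learning, a positive
#' correlation between starting values and self bias, and confidence rising
#' over T1 then decaying slightly at T2.
#'
#' @param n_participants Cohort size (default 99).
#' @param seed Master seed.
#' @return A `loop_cohort_config`.
#' @export
paper_like_preset <- function(n_participants = 99, seed = 7) {
  cohort_config(n_participants = n_participants, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Builds counterbalanced designs via [make_design()], draws generating
#' parameters per participant from the configured population distributions,
#' simulates ratings with [simulate_trajectory()] (observation noise on), and
#' produces confidence records at the four timepoints. The generating truth
#' is returned alongside and is never consumed by inference.
#'
#' @param config A [cohort_config()].
#' @return A `loop_cohort` list: `trials` (trial-record tibble), `confidence`
#'   (participant x agent x ability x timepoint), `truth` (generating
#'   parameters, wide tibble), `config`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "loop_cohort_config"))
  n <- config$n_participants
  spec <- model_spec(config$model)
  design <- make_design(n, seed = sub_seed(config$seed, "design"))
  set.seed(sub_seed(config$seed, "population"))
  truth <- purrr::map_dfr(seq_len(n), function(p) {
    draw_participant_params(config, spec, p)
  })
  trials <- purrr::map_dfr(seq_len(n), function(p) {
    pars <- unlist(truth[truth$participant == p, spec$par_names])
    simulate_trajectory(spec, pars,
                        dplyr::filter(design, .data$participant == p),
                        noise = config$sigma > 0,
                        seed = sub_seed(config$seed, paste0("traj", p))) |>
      dplyr::select(-"latent")
  })
  confidence <- sample_confidence(config, truth)
  structure(list(trials = trials, confidence = confidence, truth = truth,
                 config = config), class = "loop_cohort")
}

# One participant's generating parameters as a one-row wide tibble.
draw_participant_params <- function(config, spec, p) {
  an <- spec$alpha_names
  if (config$alpha_dist == "unif") {
    alphas <- setNames(runif(length(an), config$alpha_lo, config$alpha_hi), an)
    latent <- rnorm(1)
  } else {
    base_self <- tnorm1(1, config$alpha_mean, config$alpha_sd,
                        config$alpha_lo, config$alpha_hi)
    base_other <- tnorm1(1, config$alpha_mean, config$alpha_sd,
                         config$alpha_lo, config$alpha_hi)
    latent <- rnorm(1)
    rho <- config$sv_bias_rho
    # higher latent -> higher SV and weaker negativity (smaller delta)
    d_self <- config$delta_alpha_self +
      config$delta_sd * (-sqrt(abs(rho)) * latent +
                           sqrt(1 - abs(rho)) * rnorm(1))
    d_other <- config$delta_alpha_other + config$delta_sd * rnorm(1)
    a_t1 <- c(
      Self_pos = base_self - d_self / 2, Self_neg = base_self + d_self / 2,
      Other_pos = base_other - d_other / 2, Other_neg = base_other + d_other / 2
    )
    a_t1 <- clip01(a_t1, config$alpha_lo, config$alpha_hi)
    # T2 rates are the exact suppression multiple of the (already bounded)
    # T1 rates, so the suppression factor survives into the stored truth
    alphas <- switch(spec$id,
      M1 = c(base_self, base_other),
      M2 = rep(c(base_self, base_other), each = 2),
      M3 = a_t1,
      M4 = c(base_self, base_other, config$t2_suppression *
               c(base_self, base_other)),
      M5 = c(rep(c(base_self, base_other), each = 2),
             config$t2_suppression * rep(c(base_self, base_other), each = 2)),
      M6 = ,
      M7 = c(a_t1, config$t2_suppression * a_t1),
      M8 = c(a_t1, config$t2_suppression * a_t1),
      M9 = numeric(0)
    )
    alphas <- setNames(alphas, an)
  }
  sv_center <- clip01(config$sv_mean +
                        config$sv_sd * (sqrt(abs(config$sv_bias_rho)) * latent +
                                          sqrt(1 - abs(config$sv_bias_rho)) *
                                          rnorm(1)), 5, 95)
  sv_other <- clip01(config$sv_mean + config$sv_sd * rnorm(1), 5, 95)
  ct <- cell_table()
  center <- ifelse(ct$agent == "Self", sv_center, sv_other)
  # T2 starting values reflect T1 learning: the T2-Low cell was High at T1
  shift <- ifelse(ct$session == "T1", 0,
                  ifelse(ct$ability == "Low", config$sv_t2_shift,
                         -config$sv_t2_shift))
  svs <- setNames(clip01(center + shift +
                           if (config$sv_cell_sd > 0) rnorm(8, 0, config$sv_cell_sd)
                           else 0), spec$sv_names)
  ws <- if (spec$has_w)
    setNames(tnorm1(2, config$w_mean, config$w_sd, 0, 1), spec$w_names)
  pars <- c(alphas, ws, svs, sigma = max(config$sigma, 1e-6))
  dplyr::bind_cols(tibble::tibble(participant = p, model = spec$id,
                                  latent_factor = latent),
                   tibble::as_tibble(as.list(pars)))
}

sample_confidence <- function(config, truth) {
  spec <- model_spec(config$model)
  timepoints <- c("pre-T1", "post-T1", "pre-T2", "post-T2")
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    # learning coupling: faster T2 learners report lower post-T1 confidence
    a_t2 <- if (spec$id %in% c("M4", "M5", "M6", "M7", "M8"))
      mean(unlist(row[grep("^alpha_T2", names(row))])) else if
        (length(spec$alpha_names)) mean(unlist(row[spec$alpha_names])) else 0.2
    gain <- config$conf_gain_t1 +
      config$conf_alpha_rho * 40 * (a_t2 - config$t2_suppression * config$alpha_mean)
    base <- config$conf_pre_t1 + rnorm(1, 0, config$conf_sd)
    lvl <- c(`pre-T1` = base,
             `post-T1` = base + gain,
             `pre-T2` = base + gain - config$conf_t2_decay,
             `post-T2` = base + gain - config$conf_t2_decay / 2)
    tidyr::expand_grid(agent = LOOP_AGENTS, ability = LOOP_ABILITIES,
                       timepoint = timepoints) |>
      dplyr::mutate(participant = row$participant,
                    confidence = clip01(lvl[.data$timepoint] +
                                          rnorm(dplyr::n(), 0, config$conf_sd / 2))) |>
      dplyr::select("participant", "agent", "ability", "timepoint",
                    "confidence")
  })
}

#' @export
print.loop_cohort <- function(x, ...) {
  cat(sprintf("<loop_cohort> %d participants, model %s, %d trials\n",
              x$config$n_participants, x$config$model, nrow(x$trials)))
  invisible(x)
}
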