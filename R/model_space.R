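# The nine-model space of delta-rule belief-updating models.
#
# All learning models share the update EXP_{t+1} = EXP_t + alpha * PE_t with
# PE_t = FB_t - EXP_t, and differ only in how learning rates are partitioned
# across agent, ability, PE valence, session and PE congruency. The extended
# valence model additionally discounts updates from extreme feedback through
# a session-specific weight w on the relative normal density of the feedback
# percentile. A mean model with one constant per condition serves as the
# non-learning control. Every non-mean model frees the initial expectation
# (starting value, SV) per agent x ability cell and session.

# Canonical cell order: T1 before T2, Self before Other, High before Low.
cell_table <- function() {
  tidyr::expand_grid(session = LOOP_SESSIONS, agent = LOOP_AGENTS,
                     ability = LOOP_ABILITIES) |>
    dplyr::mutate(cell = dplyr::row_number())
}

cell_id <- function(session, agent, ability) {
  (match(session, LOOP_SESSIONS) - 1L) * 4L +
    (match(agent, LOOP_AGENTS) - 1L) * 2L +
    match(ability, LOOP_ABILITIES)
}

#' Relative normal-density weight of a feedback percentile
#'
#' Maps a feedback percentile onto the density of a normal distribution
#' centred at 50, scaled so the peak equals 1. Extreme percentiles get small
#' weights; the extended valence model multiplies them by a session weight
#' `w` to discount implausible feedback.
#'
#' @param fb Feedback percentile(s) in `[0, 100]`.
#' @param sigma_nd Scale of the density in percentile units (> 0); default 17
#'   puts the scale ends at about three standard deviations.
#' @return Weights in `(0, 1]`.
#' @export
#' @examples
#' nd_weight(50) # 1
#' nd_weight(67, 17) # exp(-1/2)
nd_weight <- function(fb, sigma_nd = 17) {
  if (any(sigma_nd <= 0)) stop("sigma_nd must be > 0", call. = FALSE)
  assert_rating(fb, "feedback")
  exp(-0.5 * ((fb - 50) / sigma_nd)^2)
}

#' Congruency of a prediction error with its condition
#'
#' A PE is congruent when its valence matches the majority valence of its
#' cell: positive in High-ability cells (70% positive feedback), negative in
#' Low cells. Ability labels are session-current, so a category that was High
#' at T1 is Low at T2 and a positive PE there becomes incongruent.
#'
#' @param ability `"High"` or `"Low"` (the cell's current ability level).
#' @param pe_sign `"+"` or `"-"` (or a numeric PE, classified by sign).
#' @return `"congruent"` or `"incongruent"`.
#' @export
congruency <- function(ability, pe_sign) {
  if (is.numeric(pe_sign)) pe_sign <- ifelse(pe_sign > 0, "+", "-")
  stopifnot(all(ability %in% LOOP_ABILITIES), all(pe_sign %in% c("+", "-")))
  ifelse((ability == "High") == (pe_sign == "+"), "congruent", "incongruent")
}

#' One delta-rule belief update
#'
#' @param exp_t Current expectation in `[0, 100]`.
#' @param fb Feedback percentile in `[0, 100]`.
#' @param alpha Learning rate in `[0, 1]`.
#' @param w Discounting weight in `[0, 1]` (0 for all models except the
#'   extended valence model).
#' @param sigma_nd Scale of the normal-density weighting curve.
#' @return Updated expectation; always between `exp_t` and `fb`.
#' @export
#' @examples
#' update_expectation(50, 70, 0.5) # 60
update_expectation <- function(exp_t, fb, alpha, w = 0, sigma_nd = 17) {
  assert_rating(exp_t, "expectation")
  assert_rating(fb, "feedback")
  stopifnot(all(alpha >= 0 & alpha <= 1), all(w >= 0 & w <= 1))
  exp_t + alpha * (fb - exp_t) * (1 - w * nd_weight(fb, sigma_nd))
}

# ---- model registry ---------------------------------------------------------

model_ids <- function() paste0("M", 1:9)

# Build an 8 x 2 matrix of alpha indices (cols: PE+, PE-) from a labelling
# function of (session, agent, ability, valence).
build_amap <- function(label_fn) {
  ct <- cell_table()
  labs <- character(0)
  m <- matrix(0L, 8L, 2L)
  for (i in seq_len(8L)) {
    for (j in 1:2) {
      lab <- label_fn(ct$session[i], ct$agent[i], ct$ability[i],
                      c("pos", "neg")[j])
      if (!lab %in% labs) labs <- c(labs, lab)
      m[i, j] <- match(lab, labs)
    }
  }
  list(amap = m, alpha_names = paste0("alpha_", labs))
}

#' Retrieve a model specification from the registry
#'
#' Models `"M1"`..`"M9"`:
#' * M1 unity: learning rates by agent (2).
#' * M2 ability: agent x ability (4).
#' * M3 valence: agent x PE valence (4).
#' * M4-M6: session-split variants of M1-M3 (4, 8, 8).
#' * M7 extended valence: M6 plus a discounting weight per session.
#' * M8 expectation: agent x congruency x session (8).
#' * M9 mean: one constant expectation per session x agent x ability cell.
#'
#' Parameter vectors are named and canonically ordered: learning rates, then
#' `w_T1`/`w_T2` (M7), then starting values (`sv_*`, or `mu_*` means for M9),
#' then the observation noise `sigma`.
#'
#' @param id Model id string.
#' @return A list with the model's name, learning-rate index map, starting
#'   value layout, and canonical parameter names.
#' @export
model_spec <- function(id) {
  if (!id %in% model_ids()) stop("unknown model id: ", id, call. = FALSE)
  ct <- cell_table()
  lab <- switch(id,
    M1 = function(s, a, b, v) a,
    M2 = function(s, a, b, v) paste(a, b, sep = "_"),
    M3 = function(s, a, b, v) paste(a, v, sep = "_"),
    M4 = function(s, a, b, v) paste(s, a, sep = "_"),
    M5 = function(s, a, b, v) paste(s, a, b, sep = "_"),
    M6 = ,
    M7 = function(s, a, b, v) paste(s, a, v, sep = "_"),
    M8 = function(s, a, b, v) paste(s, a,
      ifelse(congruency(b, c(pos = "+", neg = "-")[[v]]) == "congruent",
             "cong", "incong"), sep = "_"),
    M9 = NULL
  )
  mean_model <- id == "M9"
  if (mean_model) {
    am <- list(amap = matrix(0L, 8L, 2L), alpha_names = character(0))
  } else {
    am <- build_amap(lab)
  }
  sv_prefix <- if (mean_model) "mu" else "sv"
  sv_names <- paste(sv_prefix, ct$session, ct$agent, ct$ability, sep = "_")
  has_w <- id == "M7"
  structure(list(
    id = id,
    label = c(M1 = "Unity", M2 = "Ability", M3 = "Valence",
              M4 = "Unity (session)", M5 = "Ability (session)",
              M6 = "Valence (session)", M7 = "Extended Valence",
              M8 = "Expectation", M9 = "Mean")[[id]],
    mean_model = mean_model, has_w = has_w,
    amap = am$amap, svmap = seq_len(8L),
    cell_session = match(ct$session, LOOP_SESSIONS),
    alpha_names = am$alpha_names,
    w_names = if (has_w) c("w_T1", "w_T2") else character(0),
    sv_names = sv_names,
    par_names = c(am$alpha_names, if (has_w) c("w_T1", "w_T2"),
                  sv_names, "sigma")
  ), class = "loop_model")
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf("<loop_model %s: %s> %d free parameters\n", x$id, x$label,
              length(x$par_names)))
  invisible(x)
}

n_params <- function(spec) length(spec$par_names)

# Split a named parameter vector into the blocks the kernel consumes.
split_params <- function(spec, params) {
  stopifnot(setequal(names(params), spec$par_names))
  params <- params[spec$par_names]
  k <- length(spec$alpha_names)
  list(
    alpha = unname(params[seq_len(k)]),
    w = if (spec$has_w) unname(params[k + 1:2]) else c(0, 0),
    sv = unname(params[spec$sv_names]),
    sigma = unname(params[["sigma"]])
  )
}

# Attach canonical cell ids and sort order; returns list(trials, ord).
prepare_trials <- function(trials) {
  cell <- cell_id(trials$session, trials$agent, trials$ability)
  ord <- order(cell, trials$trial)
  list(cell = cell[ord], ord = ord, trials = trials[ord, , drop = FALSE])
}

#' Model-predicted expectation ratings for a trial table
#'
#' Runs the model's latent update over each cell's feedback sequence and
#' returns the pre-update (trial-level) prediction for every row: the cell's
#' starting value on trial 1, and thereafter the expectation updated from the
#' preceding feedback. Row order of the input is preserved.
#'
#' @param model Model id string or a [model_spec()].
#' @param params Named parameter vector in the model's canonical layout.
#' @param trials Trial tibble with `session`, `agent`, `ability`, `trial`,
#'   `feedback` columns.
#' @param sigma_nd Scale of the normal-density weighting curve.
#' @return Numeric vector of predicted ratings, aligned with `trials` rows.
#' @export
predict_expectations <- function(model, params, trials, sigma_nd = 17) {
  spec <- if (inherits(model, "loop_model")) model else model_spec(model)
  pp <- split_params(spec, params)
  pt <- prepare_trials(trials)
  wcell <- pp$w[spec$cell_session]
  pred <- .predict_cpp(pt$cell, pt$trials$feedback, spec$amap, spec$svmap,
                       wcell, pp$alpha, pp$sv, sigma_nd, spec$mean_model)
  pred[order(pt$ord)]
}

#' Pointwise log-likelihood of observed expectation ratings
#'
#' Scores each observed rating under a normal distribution truncated to
#' `[0, 100]`, centred on the model's predicted rating with scale `sigma`.
#' The first trial of each cell is scored against the starting value.
#'
#' @inheritParams predict_expectations
#' @return Per-trial log densities aligned with `trials` rows.
#' @export
pointwise_loglik <- function(model, params, trials, sigma_nd = 17) {
  spec <- if (inherits(model, "loop_model")) model else model_spec(model)
  sigma <- params[["sigma"]]
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  pred <- predict_expectations(spec, params, trials, sigma_nd)
  dtnorm_rating(trials$expectation, pred, sigma)
}

# Pointwise log-likelihood over a matrix of posterior draws (S x n_params,
# canonical column order). Returns S x n_trials in sorted-trial order along
# with the metadata of the sorted trials.
loglik_matrix <- function(spec, draws, trials, sigma_nd = 17) {
  stopifnot(ncol(draws) == n_params(spec))
  colnames(draws) <- spec$par_names
  pt <- prepare_trials(trials)
  k <- length(spec$alpha_names)
  alpha_d <- draws[, spec$alpha_names, drop = FALSE]
  w_d <- if (spec$has_w) draws[, spec$w_names, drop = FALSE] else
    matrix(0, nrow(draws), 2L)
  sv_d <- draws[, spec$sv_names, drop = FALSE]
  ll <- .loglik_draws_cpp(pt$cell, pt$trials$feedback, pt$trials$expectation,
                          spec$amap, spec$svmap, spec$cell_session,
                          alpha_d, w_d, sv_d, draws[, "sigma"],
                          sigma_nd, spec$mean_model)
  list(loglik = ll, trials = pt$trials)
}

#' Simulate a full trajectory of ratings under a model
#'
#' Closes the loop between a generating model and the adaptive task: latent
#' expectations start at the starting values, reported ratings are the latent
#' expectations plus truncated observation noise, feedback follows the
#' trailing-mean-plus-modifier rule applied to the reported ratings, and the
#' latent state updates from the latent prediction error.
#'
#' @inheritParams predict_expectations
#' @param plan Design tibble (both sessions) for one participant, as produced
#'   by [make_design()].
#' @param noise If `TRUE`, reported ratings get truncated normal observation
#'   noise `sigma`; if `FALSE`, reported ratings equal the latent state.
#' @param seed Seed for the observation noise.
#' @return A trial-record tibble with `expectation` (reported), `latent`,
#'   `feedback`, `pe` and `modifier` columns.
#' @export
simulate_trajectory <- function(model, params, plan, noise = TRUE, seed = 1,
                                sigma_nd = 17) {
  spec <- if (inherits(model, "loop_model")) model else model_spec(model)
  pp <- split_params(spec, params)
  set.seed(seed)
  out <- purrr::map_dfr(LOOP_SESSIONS, function(ss) {
    pl <- dplyr::filter(plan, .data$session == ss) |>
      dplyr::arrange(.data$trial, .data$category)
    if (!nrow(pl)) return(NULL)
    cells <- cell_id(pl$session, pl$agent, pl$ability)
    latent_state <- setNames(rep(NA_real_, 8L), as.character(1:8))
    exp_hist <- list()
    expectation <- latent <- feedback <- numeric(nrow(pl))
    for (i in seq_len(nrow(pl))) {
      c8 <- cells[i]
      key <- as.character(c8)
      if (is.na(latent_state[key])) latent_state[key] <- pp$sv[spec$svmap[c8]]
      lat <- if (spec$mean_model) pp$sv[spec$svmap[c8]] else latent_state[[key]]
      e <- if (noise) rtnorm_rating(1, lat, pp$sigma) else lat
      ref <- reference_belief(exp_hist[[key]] %||% numeric(0))
      fb <- compute_feedback(ref, pl$modifier[i])
      if (!spec$mean_model) {
        pe <- fb - lat
        if (pe != 0) {
          a <- pp$alpha[spec$amap[c8, if (pe > 0) 1L else 2L]]
          wc <- pp$w[spec$cell_session[c8]]
          latent_state[key] <- lat + a * pe * (1 - wc * nd_weight(fb, sigma_nd))
        }
      }
      expectation[i] <- e
      latent[i] <- lat
      feedback[i] <- fb
      exp_hist[[key]] <- c(exp_hist[[key]] %||% numeric(0), e)
    }
    dplyr::mutate(pl, expectation = expectation, latent = latent,
                  feedback = feedback, pe = feedback - expectation)
  })
  dplyr::select(out, "participant", "session", "agent", "ability", "category",
                "trial", "expectation", "latent", "feedback", "pe", "modifier")
}
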