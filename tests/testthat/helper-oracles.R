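# Independent brute-force oracles used across tests. Written deliberately as
# plain scalar loops, without the package's registry, index maps or C++
# kernel, so agreement is a genuine dual-route check.

# Relative normal density computed from dnorm directly.
oracle_nd <- function(fb, sigma_nd) {
  dnorm(fb, mean = 50, sd = sigma_nd) / dnorm(50, mean = 50, sd = sigma_nd)
}

# One update step, spelled out.
oracle_update <- function(exp_t, fb, alpha, w = 0, sigma_nd = 17) {
  pe <- fb - exp_t
  exp_t + alpha * pe * (1 - w * oracle_nd(fb, sigma_nd))
}

# Truncated-normal log density via pnorm/dnorm scalars.
oracle_lp <- function(x, mu, sd) {
  dnorm(x, mu, sd, log = TRUE) -
    log(pnorm(100, mu, sd) - pnorm(0, mu, sd))
}

# Model-specific learning-rate lookup by explicit branching (no index maps).
# params is the package's named canonical vector.
oracle_alpha <- function(model, params, session, agent, ability, pe) {
  v <- if (pe > 0) "pos" else "neg"
  cong <- if ((ability == "High") == (pe > 0)) "cong" else "incong"
  key <- switch(model,
    M1 = paste0("alpha_", agent),
    M2 = paste0("alpha_", agent, "_", ability),
    M3 = paste0("alpha_", agent, "_", v),
    M4 = paste0("alpha_", session, "_", agent),
    M5 = paste0("alpha_", session, "_", agent, "_", ability),
    M6 = paste0("alpha_", session, "_", agent, "_", v),
    M7 = paste0("alpha_", session, "_", agent, "_", v),
    M8 = paste0("alpha_", session, "_", agent, "_", cong)
  )
  unname(params[key])
}

# Full-trajectory prediction oracle over an arbitrary trial table.
oracle_predict_trials <- function(model, params, trials, sigma_nd = 17) {
  pred <- numeric(nrow(trials))
  key_of <- function(i) paste(trials$session[i], trials$agent[i],
                              trials$ability[i])
  state <- list()
  ord <- order(
    match(trials$session, c("T1", "T2")),
    match(trials$agent, c("Self", "Other")),
    match(trials$ability, c("High", "Low")),
    trials$trial
  )
  for (i in ord) {
    k <- key_of(i)
    if (model == "M9") {
      pred[i] <- unname(params[paste("mu", trials$session[i], trials$agent[i],
                                     trials$ability[i], sep = "_")])
      next
    }
    if (is.null(state[[k]]))
      state[[k]] <- unname(params[paste("sv", trials$session[i],
                                        trials$agent[i], trials$ability[i],
                                        sep = "_")])
    pred[i] <- state[[k]]
    pe <- trials$feedback[i] - state[[k]]
    if (pe != 0) {
      a <- oracle_alpha(model, params, trials$session[i], trials$agent[i],
                        trials$ability[i], pe)
      w <- if (model == "M7")
        unname(params[paste0("w_", trials$session[i])]) else 0
      state[[k]] <- oracle_update(state[[k]], trials$feedback[i], a, w,
                                  sigma_nd)
    }
  }
  pred
}

# Random valid parameter vector for a model (seeded by caller).
random_params <- function(spec, sigma = 6) {
  p <- c(runif(length(spec$alpha_names), 0.05, 0.9),
         if (spec$has_w) runif(2),
         runif(length(spec$sv_names), 10, 90),
         sigma)
  setNames(p, spec$par_names)
}

# Small two-session trial fixture via the generator (noise on).
small_trials <- function(model = "M3", seed = 42, sigma = 6, n_trials = 20) {
  spec <- model_spec(model)
  d <- make_design(1, seed = seed, n_trials = n_trials)
  set.seed(seed + 1)
  pars <- random_params(spec, sigma)
  simulate_trajectory(spec, pars, d, noise = TRUE, seed = seed + 2)
}
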