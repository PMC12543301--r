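# Derived statistics: valence-bias scores, learning-rate aggregates, and the
# Spearman/FDR correlation plumbing linking biases to initial expectations
# and confidence.

#' Normalized valence bias score
#'
#' `(alpha+ - alpha-) / (alpha+ + alpha-)`: positive scores mean stronger
#' belief updates after positive prediction errors, negative scores stronger
#' updates after negative ones. Scale-invariant in the pair of rates.
#'
#' @param alpha_plus,alpha_minus Learning rates (>= 0, not both 0).
#' @return Score in `[-1, 1]`; `NA` with a warning when both rates are 0.
#' @export
#' @examples
#' valence_bias(0.3, 0.1) # 0.5
valence_bias <- function(alpha_plus, alpha_minus) {
  stopifnot(all(alpha_plus >= 0), all(alpha_minus >= 0))
  denom <- alpha_plus + alpha_minus
  bad <- denom == 0
  if (any(bad)) warning("valence bias undefined where both rates are 0")
  out <- (alpha_plus - alpha_minus) / denom
  out[bad] <- NA_real_
  out
}

#' Learning rate averaged over PE valence
#'
#' @param alpha_plus,alpha_minus Learning rates for positive and negative
#'   prediction errors.
#' @return Their arithmetic mean.
#' @export
mean_learning_rate <- function(alpha_plus, alpha_minus) {
  (alpha_plus + alpha_minus) / 2
}

#' Per-participant valence-bias table from extended-valence-model fits
#'
#' Extracts the posterior-mean valence-specific learning rates of each fit
#' and computes bias scores and mean learning rates per agent and session.
#'
#' @param fits Tibble from [fit_cohort()] restricted to a model with
#'   session- and valence-specific rates (`M6` or `M7`).
#' @return A tibble: `participant`, `session`, `agent`, `alpha_pos`,
#'   `alpha_neg`, `mean_alpha`, `bias`.
#' @export
valence_bias_scores <- function(fits) {
  stopifnot(all(fits$model %in% c("M6", "M7")))
  purrr::map_dfr(fits$fit, function(f) {
    est <- f$estimates
    tidyr::expand_grid(session = LOOP_SESSIONS, agent = LOOP_AGENTS) |>
      dplyr::mutate(
        participant = f$participant,
        alpha_pos = unname(est[paste("alpha", .data$session, .data$agent, "pos", sep = "_")]),
        alpha_neg = unname(est[paste("alpha", .data$session, .data$agent, "neg", sep = "_")]),
        mean_alpha = mean_learning_rate(.data$alpha_pos, .data$alpha_neg),
        bias = valence_bias(.data$alpha_pos, .data$alpha_neg)
      )
  }) |>
    dplyr::select("participant", "session", "agent", "alpha_pos", "alpha_neg",
                  "mean_alpha", "bias")
}

#' Initial expectation ratings per participant
#'
#' The first expectation rating per cell. At T1 the two ability cells of an
#' agent are averaged (the manipulation has not yet differentiated them); at
#' T2 they are kept separate by former ability level (the T1 ability of the
#' category).
#'
#' @param trials Trial tibble (both sessions).
#' @return A tibble: `participant`, `agent`, `session`, `scope` (`"mean"` at
#'   T1; `"former_High"` / `"former_Low"` at T2), `initial_expectation`.
#' @export
initial_expectations <- function(trials) {
  first <- trials |>
    dplyr::group_by(.data$participant, .data$session, .data$agent,
                    .data$ability, .data$category) |>
    dplyr::slice_min(.data$trial, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  t1 <- first |>
    dplyr::filter(.data$session == "T1") |>
    dplyr::group_by(.data$participant, .data$agent) |>
    dplyr::summarise(initial_expectation = mean(.data$expectation),
                     .groups = "drop") |>
    dplyr::mutate(session = "T1", scope = "mean")
  # at T2 the current ability is the flip of the T1 ability of the category
  t2 <- first |>
    dplyr::filter(.data$session == "T2") |>
    dplyr::mutate(scope = ifelse(.data$ability == "High", "former_Low",
                                 "former_High"),
                  initial_expectation = .data$expectation) |>
    dplyr::select("participant", "agent", "session", "scope",
                  "initial_expectation")
  dplyr::bind_rows(t1, t2) |>
    dplyr::select("participant", "agent", "session", "scope",
                  "initial_expectation")
}

#' Spearman correlations with FDR control over a family of tests
#'
#' Runs two-sided Spearman rank correlations over a declared family of
#' variable pairs, reports Fisher-z 95% confidence intervals with the
#' rank-correlation variance correction, and Benjamini-Hochberg adjusted
#' p-values across the family.
#'
#' @param data A data frame of per-participant values.
#' @param pairs A list of 2-element character vectors naming the columns of
#'   each test in the family; a single pair may be given directly.
#' @param conf_level Confidence level for the intervals.
#' @return A tibble: `x`, `y`, `n`, `rho`, `ci_low`, `ci_high`, `p`, `p_fdr`.
#' @export
#' @examples
#' d <- data.frame(a = 1:10, b = (1:10)^2, c = rnorm(10))
#' correlate(d, list(c("a", "b"), c("a", "c")))
correlate <- function(data, pairs, conf_level = 0.95) {
  if (is.character(pairs)) pairs <- list(pairs)
  res <- purrr::map_dfr(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
    if (sd(x) == 0 || sd(y) == 0)
      return(tibble::tibble(x = pr[1], y = pr[2], n = n, rho = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_))
    ct <- cor.test(x, y, method = "spearman", exact = FALSE)
    rho <- unname(ct$estimate)
    # Fisher z with the Fieller-Hartley-Pearson variance for rank correlations
    se <- sqrt((1 + rho^2 / 2) / (n - 3))
    zq <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(rho) + c(-1, 1) * zq * se)
    tibble::tibble(x = pr[1], y = pr[2], n = n, rho = rho,
                   ci_low = ci[1], ci_high = ci[2], p = unname(ct$p.value))
  })
  dplyr::mutate(res, p_fdr = p.adjust(.data$p, method = "BH"))
}
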