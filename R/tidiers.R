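# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
tidy.loop_fit <- function(x, ...) {
  x$summary |>
    dplyr::rename(estimate = "mean", std.error = "sd")
}

#' @export
glance.loop_fit <- function(x, ...) {
  pp <- posterior_predictive(x)
  tibble::tibble(
    model = x$model,
    participant = x$participant,
    n_trials = nrow(x$trials),
    n_draws = if (is.null(x$draws)) NA_integer_ else nrow(x$draws),
    r_squared = attr(pp, "r_squared"),
    max_rhat = suppressWarnings(max(x$summary$rhat, na.rm = TRUE)),
    min_n_eff = suppressWarnings(min(x$summary$n_eff, na.rm = TRUE)),
    converged = !"non_convergence" %in% x$flags,
    sampler = x$config$sampler
  )
}

#' @export
tidy.loop_bms <- function(x, ...) x$table

#' @export
glance.loop_bms <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants,
                 n_models = nrow(x$table),
                 bor = x$bor,
                 winner = x$table$model[which.max(x$table$pxp)],
                 winner_pxp = max(x$table$pxp))
}

#' @export
tidy.loop_loo <- function(x, ...) x$pointwise

#' @export
glance.loop_loo <- function(x, ...) {
  tibble::tibble(elpd = x$elpd, lpd = x$lpd, n_trials = x$n_trials,
                 n_draws = x$n_draws, frac_khat_high = x$frac_khat_high)
}

#' @export
autoplot.loop_fit <- function(object, ...) {
  pp <- posterior_predictive(object)
  long <- tidyr::pivot_longer(pp, c("observed", "predicted"),
                              names_to = "series", values_to = "rating")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$rating,
                                     colour = .data$ability,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$agent),
                        cols = ggplot2::vars(.data$session)) +
    ggplot2::labs(x = "trial", y = "expectation rating (percentile)",
                  title = sprintf("Posterior predictive overlay (%s)",
                                  object$model)) +
    ggplot2::ylim(0, 100)
}

#' @export
autoplot.loop_bms <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$model, y = .data$pxp)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$frequency), colour = "red") +
    ggplot2::labs(y = "protected exceedance probability",
                  caption = sprintf("points: expected frequencies; BOR = %.3g",
                                    object$bor)) +
    ggplot2::ylim(0, 1)
}

#' Mean expectation trajectories of a cohort
#'
#' @param trials Trial-record tibble.
#' @return A ggplot of mean ratings over trials by session, agent, ability.
#' @export
plot_learning_curves <- function(trials) {
  means <- trials |>
    dplyr::group_by(.data$session, .data$agent, .data$ability, .data$trial) |>
    dplyr::summarise(expectation = mean(.data$expectation), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$trial, y = .data$expectation,
                                      colour = .data$ability)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$agent),
                        cols = ggplot2::vars(.data$session)) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "mean expectation rating (percentile)")
}
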