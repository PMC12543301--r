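# Readers, writers, and the end-to-end pipeline driver.

trial_schema <- c("participant", "session", "agent", "ability", "category",
                  "trial", "expectation", "feedback", "pe", "modifier")

#' Write a trial table to CSV
#'
#' @param trials Trial-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(dplyr::select(trials, dplyr::all_of(trial_schema)), path)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Checks the column schema, the factor levels of `session`, `agent` and
#' `ability`, the `[0, 100]` range of ratings and feedback, the exactness of
#' `pe = feedback - expectation`, and that every participant-session-cell
#' carries a full block of trials. Violations are reported with row and
#' column.
#'
#' @param path CSV path written by [write_trials()] (or matching its schema).
#' @param n_trials Expected trials per cell and session.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, n_trials = 20L) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(trial_schema, names(tr))
  if (length(missing_cols))
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_level <- function(col, levels) {
    bad <- which(!tr[[col]] %in% levels)
    if (length(bad))
      stop(sprintf("row %d, column '%s': value '%s' not in {%s}", bad[1], col,
                   tr[[col]][bad[1]], paste(levels, collapse = ", ")),
           call. = FALSE)
  }
  check_level("session", LOOP_SESSIONS)
  check_level("agent", LOOP_AGENTS)
  check_level("ability", LOOP_ABILITIES)
  for (col in c("expectation", "feedback")) {
    bad <- which(!is.finite(tr[[col]]) | tr[[col]] < 0 | tr[[col]] > 100)
    if (length(bad))
      stop(sprintf("row %d, column '%s': value %s outside [0, 100]", bad[1],
                   col, format(tr[[col]][bad[1]])), call. = FALSE)
  }
  bad <- which(abs(tr$pe - (tr$feedback - tr$expectation)) > 1e-8)
  if (length(bad))
    stop(sprintf("row %d, column 'pe': not feedback - expectation", bad[1]),
         call. = FALSE)
  counts <- dplyr::count(tr, .data$participant, .data$session, .data$agent,
                         .data$ability)
  bad <- which(counts$n != n_trials)
  if (length(bad))
    stop(sprintf("participant %s, session %s, %s-%s: %d trials (expected %d)",
                 format(counts$participant[bad[1]]), counts$session[bad[1]],
                 counts$agent[bad[1]], counts$ability[bad[1]],
                 counts$n[bad[1]], n_trials), call. = FALSE)
  tr
}

#' Serialize a design (or any cohort artifact) to JSON
#'
#' @param x List or tibble to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains cohort simulation (or ingestion of a trial CSV), per-participant
#' fitting over a model subset, per-session PSIS-LOO and random-effects
#' Bayesian model selection, valence-bias scores from the winning-family
#' model, and the correlation analyses. Deterministic given the seeds; a
#' manifest (config fingerprint, seed, package version) accompanies any
#' written artifact.
#'
#' @param cohort A `loop_cohort` (from [sample_cohort()]), or `NULL` to read
#'   `trials_path`.
#' @param trials_path Optional CSV of trials used when `cohort` is `NULL`.
#' @param models Model ids to fit and compare.
#' @param config A [fit_config()].
#' @param bias_model Model whose fits feed the valence-bias analyses (must be
#'   in `models`; default `"M7"`).
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `evidence_*.csv`, `bms_*.json`, `bias_scores.csv`, `correlations.csv`
#'   and `manifest.json`.
#' @return A `loop_report` list: `fits`, per-session `bms`, `fixed_effects`,
#'   `bias`, `initial`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, trials_path = NULL,
                         models = c("M1", "M3", "M7", "M9"),
                         config = fit_config(sampler = "map"),
                         bias_model = "M7", out_dir = NULL) {
  if (is.null(cohort) && is.null(trials_path))
    stop("pipeline stage 'ingest': provide a cohort or a trials_path",
         call. = FALSE)
  trials <- if (!is.null(cohort)) cohort$trials else read_trials(trials_path)
  stopifnot(bias_model %in% models)

  fits <- run_stage("fit", fit_cohort(trials, models, config, slim = TRUE))
  bms <- lapply(setNames(LOOP_SESSIONS, LOOP_SESSIONS), function(ss) {
    ev <- run_stage("loo", loo_evidence(fits, session = ss))
    run_stage("bms", rfx_bms(ev, seed = sub_seed(config$seed, paste0("bms", ss))))
  })
  evidence <- run_stage("loo", loo_evidence(fits))
  fixed <- fixed_effect_compare(evidence)

  bias_fits <- dplyr::filter(fits, .data$model == bias_model)
  bias <- run_stage("metrics", valence_bias_scores(bias_fits))
  initial <- initial_expectations(trials)
  corr_df <- bias |>
    dplyr::filter(.data$session == "T1") |>
    dplyr::inner_join(dplyr::filter(initial, .data$session == "T1"),
                      by = c("participant", "agent", "session")) |>
    tidyr::pivot_wider(id_cols = "participant",
                       names_from = "agent",
                       values_from = c("bias", "initial_expectation"))
  correlations <- run_stage("metrics", correlate(corr_df,
    list(c("initial_expectation_Self", "bias_Self"),
         c("initial_expectation_Other", "bias_Other"))))

  manifest <- list(
    package = "looplearn",
    version = as.character(utils::packageVersion("looplearn")),
    seed = config$seed, sampler = config$sampler, models = models,
    n_participants = length(unique(trials$participant)),
    config_hash = rlang::hash(list(models, unclass(config), bias_model))
  )
  report <- structure(list(fits = fits, bms = bms, fixed_effects = fixed,
                           evidence = evidence, bias = bias,
                           initial = initial, correlations = correlations,
                           manifest = manifest), class = "loop_report")
  if (!is.null(out_dir)) write_report(report, trials, out_dir)
  report
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_report <- function(report, trials, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  for (ss in names(report$bms)) {
    b <- report$bms[[ss]]
    jsonlite::write_json(
      list(table = b$table, bor = b$bor, alpha = as.list(b$alpha)),
      file.path(out_dir, paste0("bms_", ss, ".json")),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  ev <- tibble::as_tibble(report$evidence) |>
    dplyr::mutate(participant = rownames(report$evidence), .before = 1)
  readr::write_csv(ev, file.path(out_dir, "evidence.csv"))
  readr::write_csv(report$bias, file.path(out_dir, "bias_scores.csv"))
  readr::write_csv(report$correlations, file.path(out_dir, "correlations.csv"))
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.loop_report <- function(x, ...) {
  cat("<loop_report>\n")
  for (ss in names(x$bms))
    cat(sprintf("  %s winner: %s (pxp = %.3f, BOR = %.3g)\n", ss,
                x$bms[[ss]]$table$model[which.max(x$bms[[ss]]$table$pxp)],
                max(x$bms[[ss]]$table$pxp), x$bms[[ss]]$bor))
  invisible(x)
}
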