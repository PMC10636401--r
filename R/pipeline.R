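#' Read a run configuration from YAML
#'
#' The file may set `mode` (`simulate`, `analyze`, `full`), `trials_csv`
#' (analyze mode input), `n_participants`, `n_exemplars`, `seed`
#' (mandatory for any simulation), `rt_log_base` (`e`/`10`),
#' `outlier_threshold_sd`, `fit_method` (`mle`/`ls`), `pmu_method`
#' (`waveform_centroid`/`quadratic_vertex`), and `means`/`sds` overrides
#' for the cohort population.
#'
#' @param path YAML file.
#' @return A run-config list (see [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Assemble a run configuration
#'
#' @param mode `"full"` (simulate then analyze, default), `"simulate"`, or
#'   `"analyze"` (requires `trials_csv`).
#' @param seed Integer seed; required unless `mode = "analyze"`.
#' @param trials_csv Input trial CSV for analyze mode.
#' @param n_participants,n_exemplars,means,sds,rt_log_base Passed to
#'   [cohort_config()].
#' @param outlier_threshold_sd RT exclusion threshold (default 3).
#' @param fit_method Logistic fitting criterion, `"mle"` or `"ls"`.
#' @param pmu_method `"waveform_centroid"` or `"quadratic_vertex"`.
#' @return Run-config list.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       seed = NULL, trials_csv = NULL,
                       n_participants = 75, n_exemplars = 7,
                       means = list(), sds = list(),
                       rt_log_base = "e",
                       outlier_threshold_sd = 3,
                       fit_method = c("mle", "ls"),
                       pmu_method = c("waveform_centroid", "quadratic_vertex")) {
  mode <- match.arg(mode)
  fit_method <- match.arg(fit_method)
  pmu_method <- match.arg(pmu_method)
  stopifnot(outlier_threshold_sd > 0)
  if (mode != "analyze" && is.null(seed)) {
    stop("`seed` is required for any simulating mode", call. = FALSE)
  }
  if (mode == "analyze" && is.null(trials_csv)) {
    stop("analyze mode requires `trials_csv`", call. = FALSE)
  }
  list(mode = mode, seed = seed, trials_csv = trials_csv,
       n_participants = n_participants, n_exemplars = n_exemplars,
       means = means, sds = sds, rt_log_base = rt_log_base,
       outlier_threshold_sd = outlier_threshold_sd,
       fit_method = fit_method, pmu_method = pmu_method)
}

#' Run the full anchoring analysis pipeline
#'
#' Orchestrates simulate (or load) -> RT outlier exclusion -> 49-cell
#' aggregation -> logistic and linear psychophysical fits -> PMU extraction
#' -> repeated-measures ANOVAs and linear anchor contrasts, writing every
#' stage's table as CSV into `out_dir` together with a human-readable
#' report and a MANIFEST of completed stages.
#'
#' @param config Run-config list from [run_config()] or [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("anchordecomp %s | started %s",
           as.character(utils::packageVersion("anchordecomp")),
           format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  log_line("config: %s", paste(utils::capture.output(utils::str(config)),
                               collapse = " "))

  truth <- NULL
  if (config$mode %in% c("full", "simulate")) {
    cohort <- cohort_config(
      n_participants = config$n_participants,
      n_exemplars = config$n_exemplars, seed = config$seed,
      means = config$means, sds = config$sds,
      rt_log_base = if (config$rt_log_base == "10") "10" else "e"
    )
    sim <- simulate_experiment(cohort)
    trials <- sim$trials
    truth <- sim$params
    write_trials(trials, file.path(out_dir, "trials.csv"))
    readr::write_csv(truth, file.path(out_dir, "observer_params_true.csv"))
    note("simulate")
    if (config$mode == "simulate") {
      log_line("simulate-only run complete: %d trials", nrow(trials))
      return(invisible(list(trials = trials, truth = truth)))
    }
  } else {
    trials <- read_trials(config$trials_csv)
    note("load")
  }

  excl <- exclude_rt_outliers(trials, config$outlier_threshold_sd)
  readr::write_csv(excl$report, file.path(out_dir, "exclusion_report.csv"))
  cells <- aggregate_cells(excl$trials,
                           log_base = if (config$rt_log_base == "10") "10" else "e")
  readr::write_csv(cells, file.path(out_dir, "cell_summaries.csv"))
  note("aggregate")

  fits_rel <- fit_all_relative(cells, method = config$fit_method)
  readr::write_csv(fits_rel, file.path(out_dir, "fits_relative.csv"))
  fits_abs <- fit_all_absolute(cells)
  readr::write_csv(fits_abs, file.path(out_dir, "fits_absolute.csv"))
  note("psychometric")
  log_line("relative fits: %d rows, good-fit (R2 > .89) fraction %.3f",
           nrow(fits_rel), attr(fits_rel, "good_fit_fraction"))
  log_line("absolute fits: %d rows, mean R2 %.3f",
           nrow(fits_abs), attr(fits_abs, "mean_r_squared"))

  pmus <- pmu_table(cells, method = config$pmu_method)
  readr::write_csv(pmus, file.path(out_dir, "pmu.csv"))
  note("pmu")

  n_participants <- length(unique(trials$participant_id))
  inference <- NULL
  if (n_participants >= 2) {
    inference <- run_inference(cells, fits_rel, fits_abs, pmus)
    readr::write_csv(inference$anova, file.path(out_dir, "anova.csv"))
    readr::write_csv(
      dplyr::select(inference$contrast_by_level, -"scores"),
      file.path(out_dir, "contrast_by_level.csv")
    )
    note("inference")
  } else {
    log_line("inference skipped: insufficient participants (%d)", n_participants)
  }

  results <- list(trials = trials, truth = truth, cells = cells,
                  exclusions = excl$report, fits_relative = fits_rel,
                  fits_absolute = fits_abs, pmu = pmus,
                  inference = inference, config = config)
  report <- make_report(results)
  writeLines(report, file.path(out_dir, "report.txt"))
  note("report")
  log_line("run complete")
  invisible(results)
}

# All within-subject inferential analyses on the fitted indices.
run_inference <- function(cells, fits_rel, fits_abs, pmus) {
  effects <- list()
  tw <- rm_anova_twoway(cells, "p_larger", on_incomplete = "drop")
  tw$analysis <- "p_larger_7x7"
  tw_est <- rm_anova_twoway(cells, "mean_estimate", on_incomplete = "drop")
  tw_est$analysis <- "estimate_7x7"
  ow <- function(df, value, label) {
    out <- rm_anova_oneway(df, value, on_incomplete = "drop")
    out$analysis <- label
    out
  }
  rel_ok <- fits_rel |> dplyr::filter(.data$degenerate_code == "none",
                                      .data$converged)
  abs_ok <- fits_abs |> dplyr::filter(.data$valid_slope)
  anova_tab <- dplyr::bind_rows(
    tw, tw_est,
    ow(rel_ok, "pse", "relative_pse"),
    ow(rel_ok, "dl", "relative_dl"),
    ow(abs_ok, "pse", "absolute_pse"),
    ow(abs_ok, "dl", "absolute_dl"),
    ow(dplyr::filter(pmus, .data$phase == "relative", !is.na(.data$pmu)),
       "pmu", "pmu_relative"),
    ow(dplyr::filter(pmus, .data$phase == "absolute", !is.na(.data$pmu)),
       "pmu", "pmu_absolute")
  )
  contrast_overall <- linear_contrast(cells, "p_larger")
  contrast_by_level <- linear_contrast(cells, "p_larger", by = "true_pct")
  list(anova = anova_tab, contrast_overall = contrast_overall,
       contrast_by_level = contrast_by_level)
}

#' Render the run report
#'
#' Summarises each stage in the order of the analyses: relative judgments
#' (logistic fits, PSE/DL by anchor), absolute estimates (linear fits),
#' reaction times (PMU by anchor and phase), ANOVAs and contrasts, plus
#' directional-pattern checks of the expected anchoring signatures.
#'
#' @param results Stage-results list from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(results) {
  lines <- c("Anchoring decomposition run report",
             strrep("=", 40), "")
  per_anchor <- function(df, value) {
    df |>
      dplyr::filter(!is.na(.data[[value]])) |>
      dplyr::group_by(.data$anchor) |>
      dplyr::summarise(mean = mean(.data[[value]]), n = dplyr::n(),
                       .groups = "drop")
  }
  fmt_tab <- function(tab) {
    sprintf("  anchor %2d: %8.3f  (n = %d)", tab$anchor, tab$mean, tab$n)
  }
  dir_check <- function(v, direction, label) {
    d <- diff(v)
    ok <- if (direction == "dec") all(d < 0) else all(d > 0)
    trend <- if (all(abs(d) < 1e-8)) "no effect" else if (ok) "PASS" else "not monotone"
    sprintf("  [%s] %s", trend, label)
  }
  rel <- results$fits_relative
  if (!is.null(rel)) {
    pse_t <- per_anchor(rel, "pse"); dl_t <- per_anchor(rel, "dl")
    lines <- c(lines, "Relative judgments (logistic psychometric fits)",
               sprintf("  good-fit fraction (R2 > .89): %.3f",
                       attr(rel, "good_fit_fraction")),
               "  mean PSE by anchor:", fmt_tab(pse_t),
               "  mean DL by anchor:", fmt_tab(dl_t), "")
  }
  ab <- results$fits_absolute
  if (!is.null(ab)) {
    pse_t <- per_anchor(ab, "pse"); dl_t <- per_anchor(ab, "dl")
    lines <- c(lines, "Absolute estimates (linear psychophysical fits)",
               sprintf("  mean R2: %.3f", attr(ab, "mean_r_squared")),
               "  mean PSE by anchor:", fmt_tab(pse_t),
               "  mean DL by anchor:", fmt_tab(dl_t), "")
  }
  pm <- results$pmu
  if (!is.null(pm)) {
    for (ph in c("relative", "absolute")) {
      t <- per_anchor(dplyr::filter(pm, .data$phase == ph), "pmu")
      lines <- c(lines, sprintf("PMU by anchor (%s phase):", ph), fmt_tab(t))
    }
    lines <- c(lines, "")
  }
  inf <- results$inference
  if (!is.null(inf)) {
    lines <- c(lines, "Repeated-measures ANOVAs:")
    for (i in seq_len(nrow(inf$anova))) {
      e <- inf$anova[i, ]
      lines <- c(lines, sprintf("  %-14s %-10s %s", e$analysis, e$effect,
                                format_effect(e)))
    }
    lines <- c(lines, "",
               sprintf("Linear anchor contrast on p(larger): mean score %.3f, t(%.0f) = %.2f",
                       inf$contrast_overall$mean_score,
                       inf$contrast_overall$df, inf$contrast_overall$t))
    by_lv <- inf$contrast_by_level
    peak <- by_lv$true_pct[which.max(abs(by_lv$mean_score))]
    lines <- c(lines, sprintf("  stratified contrast magnitude peaks at true_pct = %d",
                              as.integer(peak)), "")
  } else {
    lines <- c(lines, "Inference: skipped (insufficient participants)", "")
  }
  lines <- c(lines, "Directional pattern checks:")
  if (!is.null(rel)) {
    lines <- c(lines,
               dir_check(per_anchor(rel, "pse")$mean, "dec",
                         "relative PSE decreases with anchor"),
               dir_check(per_anchor(rel, "dl")$mean, "inc",
                         "relative DL increases with anchor"))
  }
  if (!is.null(pm)) {
    lines <- c(lines,
               dir_check(per_anchor(dplyr::filter(pm, .data$phase == "relative"),
                                    "pmu")$mean, "inc",
                         "relative PMU increases with anchor"),
               dir_check(per_anchor(dplyr::filter(pm, .data$phase == "absolute"),
                                    "pmu")$mean, "dec",
                         "absolute PMU decreases with anchor"))
  }
  lines
}
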