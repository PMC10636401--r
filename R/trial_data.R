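trial_columns <- function() {
  c(participant_id = "character", set_index = "integer",
    anchor = "double", true_pct = "double",
    stimulus_class = "character", category_label = "character",
    exemplar_index = "integer",
    relative_response = "integer", rt_relative_ms = "double",
    absolute_estimate = "double", rt_absolute_ms = "double")
}

#' Write a trial table to CSV
#'
#' @param trials Trial tibble as produced by [simulate_experiment()].
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  cols <- names(trial_columns())
  missing_cols <- setdiff(cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the schema (every documented column present, cells parsable)
#' and, by default, that anchors and true percentages lie on the 7-level
#' 20-80% grid.
#'
#' @param path CSV path with the documented trial-table header.
#' @param strict_grid If `TRUE` (default) anchors/true percentages off the
#'   design grid raise an error; if `FALSE` they only warn, for non-standard
#'   designs.
#' @return Typed trial tibble; input row order preserved.
#' @export
read_trials <- function(path, strict_grid = TRUE) {
  spec <- readr::cols(
    participant_id = readr::col_character(),
    set_index = readr::col_integer(),
    anchor = readr::col_double(),
    true_pct = readr::col_double(),
    stimulus_class = readr::col_character(),
    category_label = readr::col_character(),
    exemplar_index = readr::col_integer(),
    relative_response = readr::col_integer(),
    rt_relative_ms = readr::col_double(),
    absolute_estimate = readr::col_double(),
    rt_absolute_ms = readr::col_double()
  )
  trials <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(names(trial_columns()), names(trials))
  if (length(missing_cols) > 0) {
    stop("trial file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    stop("unparsable cell(s) in ", path, ": row ", probs$row[1],
         ", expected ", probs$expected[1], call. = FALSE)
  }
  off_grid <- !(trials$anchor %in% design_levels()) |
    !(trials$true_pct %in% design_levels())
  if (any(off_grid)) {
    msg <- paste0(sum(off_grid), " row(s) have anchor/true_pct off the ",
                  "20-80% by 10 design grid (first at row ", which(off_grid)[1], ")")
    if (strict_grid) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (any(trials$rt_relative_ms <= 0) || any(trials$rt_absolute_ms <= 0)) {
    stop("reaction times must be strictly positive", call. = FALSE)
  }
  if (any(trials$absolute_estimate < 0 | trials$absolute_estimate > 100)) {
    stop("absolute estimates must lie in [0, 100]", call. = FALSE)
  }
  trials
}

#' Flag reaction-time outliers
#'
#' Applies the SD-criterion exclusion rule: per participant and per phase
#' (relative, absolute) independently, a trial whose raw RT deviates from
#' that participant's phase mean by more than `threshold_sd` standard
#' deviations is flagged. A flagged trial is dropped only from that phase's
#' aggregates; the other phase keeps it. The rule is applied in a single
#' pass (mean and SD are not recomputed after exclusion).
#'
#' @param trials Trial tibble.
#' @param threshold_sd Exclusion threshold in SD units (default 3).
#' @return List with `trials` (input plus logical `exclude_rel`,
#'   `exclude_abs`) and `report` (per participant x phase: `n_in`,
#'   `n_excluded`).
#' @export
exclude_rt_outliers <- function(trials, threshold_sd = 3) {
  stopifnot(threshold_sd > 0)
  flag <- function(rt) {
    m <- mean(rt)
    s <- stats::sd(rt)
    if (length(rt) < 2 || is.na(s) || s == 0) return(rep(FALSE, length(rt)))
    abs(rt - m) > threshold_sd * s
  }
  trials <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      exclude_rel = flag(.data$rt_relative_ms),
      exclude_abs = flag(.data$rt_absolute_ms)
    ) |>
    dplyr::ungroup()
  report <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      relative = sum(.data$exclude_rel),
      absolute = sum(.data$exclude_abs),
      n_in = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("relative", "absolute"),
                        names_to = "phase", values_to = "n_excluded") |>
    dplyr::select("participant_id", "phase", "n_in", "n_excluded")
  list(trials = trials, report = report)
}

#' Aggregate trials to the 49 design-cell summaries
#'
#' For each participant x anchor x true-percentage cell computes the
#' proportion of "larger" responses (over trials retained for the relative
#' phase), the mean absolute estimate and mean log RTs (over trials retained
#' for the respective phase). Cells whose trials were all excluded for a
#' phase carry `NA` for that phase's summaries.
#'
#' @param trials Trial tibble carrying `exclude_rel` / `exclude_abs` flags
#'   (from [exclude_rt_outliers()]); if absent, nothing is excluded.
#' @param log_base `"e"` (natural, default) or `"10"`.
#' @return Tibble with one row per participant x anchor x true_pct:
#'   `n_trials`, `n_excluded_rel`, `n_excluded_abs`, `p_larger`,
#'   `mean_estimate`, `mean_logrt_rel`, `mean_logrt_abs`.
#' @export
aggregate_cells <- function(trials, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  lg <- if (log_base == "10") log10 else log
  if (!all(c("exclude_rel", "exclude_abs") %in% names(trials))) {
    trials$exclude_rel <- FALSE
    trials$exclude_abs <- FALSE
  }
  mean_or_na <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_
  cells <- trials |>
    dplyr::group_by(.data$participant_id, .data$anchor, .data$true_pct) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_excluded_rel = sum(.data$exclude_rel),
      n_excluded_abs = sum(.data$exclude_abs),
      p_larger = mean_or_na(.data$relative_response, !.data$exclude_rel),
      mean_estimate = mean_or_na(.data$absolute_estimate, !.data$exclude_abs),
      mean_logrt_rel = mean_or_na(lg(.data$rt_relative_ms), !.data$exclude_rel),
      mean_logrt_abs = mean_or_na(lg(.data$rt_absolute_ms), !.data$exclude_abs),
      .groups = "drop"
    )
  empty <- cells$n_trials - cells$n_excluded_rel == 0 |
    cells$n_trials - cells$n_excluded_abs == 0
  if (any(empty)) {
    warning(sum(empty), " design cell(s) lost all trials for at least one phase",
            call. = FALSE)
  }
  cells
}
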