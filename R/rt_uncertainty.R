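#' Build mean log-RT curves by feature percentage
#'
#' Treats the true stimulus levels as bins: one 7-point curve of mean log RT
#' against true feature percentage per participant x anchor, for the chosen
#' response phase. Curves with fewer than 3 non-missing levels are flagged
#' unusable for PMU extraction.
#'
#' @param cells Cell-summary tibble from [aggregate_cells()].
#' @param phase `"relative"` or `"absolute"`.
#' @return Tibble with one row per participant x anchor x level: `phase`,
#'   `true_pct`, `logrt`, `n`, plus a per-curve `usable` flag.
#' @export
build_rt_curves <- function(cells, phase = c("relative", "absolute")) {
  phase <- match.arg(phase)
  ycol <- if (phase == "relative") "mean_logrt_rel" else "mean_logrt_abs"
  ncol_ <- if (phase == "relative") "n_excluded_rel" else "n_excluded_abs"
  cells |>
    dplyr::transmute(
      .data$participant_id, .data$anchor, phase = phase,
      true_pct = .data$true_pct,
      logrt = .data[[ycol]],
      n = .data$n_trials - .data[[ncol_]]
    ) |>
    dplyr::arrange(.data$participant_id, .data$anchor, .data$true_pct) |>
    dplyr::group_by(.data$participant_id, .data$anchor) |>
    dplyr::mutate(usable = sum(!is.na(.data$logrt)) >= 3) |>
    dplyr::ungroup()
}

#' Point of maximal uncertainty by waveform-moment (centroid) analysis
#'
#' Subtracts the curve minimum as baseline and takes the first moment of the
#' remaining waveform: `pmu = sum(x * w) / sum(w)` with
#' `w = logrt - min(logrt)`. The centroid always lies inside the stimulus
#' range; a flat curve carries no information and yields a flagged `NA`.
#'
#' @param x True-percentage levels (>= 3 non-missing).
#' @param y Mean log RT per level.
#' @return One-row tibble: `pmu`, `method`, `baseline`, `flag` (`"ok"` or
#'   `"flat"`).
#' @export
pmu_waveform <- function(x, y) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 non-missing levels", call. = FALSE)
  baseline <- min(y)
  w <- y - baseline
  if (sum(w) == 0) {
    return(tibble::tibble(pmu = NA_real_, method = "waveform_centroid",
                          baseline = baseline, flag = "flat"))
  }
  tibble::tibble(pmu = sum(x * w) / sum(w), method = "waveform_centroid",
                 baseline = baseline, flag = "ok")
}

#' Point of maximal uncertainty by quadratic-vertex fit
#'
#' OLS quadratic fit `y = c0 + c1 x + c2 x^2`; the PMU is the vertex
#' `-c1 / (2 c2)` when the parabola opens downward (`c2 < 0`). An
#' upward-opening fit has no interior peak and is flagged; a vertex outside
#' the stimulus range is clamped to \[20, 80\] with a flag.
#'
#' @inheritParams pmu_waveform
#' @return One-row tibble: `pmu`, `method`, `baseline`, `flag` (`"ok"`,
#'   `"no_peak"`, `"clamped"`).
#' @export
pmu_quadratic <- function(x, y) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 non-missing levels", call. = FALSE)
  b <- unname(stats::coef(stats::lm(y ~ x + I(x^2))))
  baseline <- min(y)
  if (!is.finite(b[3]) || b[3] >= 0) {
    return(tibble::tibble(pmu = NA_real_, method = "quadratic_vertex",
                          baseline = baseline, flag = "no_peak"))
  }
  v <- -b[2] / (2 * b[3])
  flag <- "ok"
  if (v < 20 || v > 80) {
    v <- min(max(v, 20), 80)
    flag <- "clamped"
  }
  tibble::tibble(pmu = v, method = "quadratic_vertex",
                 baseline = baseline, flag = flag)
}

#' PMU table for every participant x anchor x phase
#'
#' Builds the log-RT curves for both phases and applies the configured PMU
#' estimator to every usable curve.
#'
#' @param cells Cell-summary tibble from [aggregate_cells()].
#' @param method `"waveform_centroid"` (default) or `"quadratic_vertex"`.
#' @return Tidy tibble: `participant_id`, `anchor`, `phase`, `pmu`,
#'   `method`, `flag`.
#' @export
pmu_table <- function(cells, method = c("waveform_centroid", "quadratic_vertex")) {
  method <- match.arg(method)
  est <- if (method == "waveform_centroid") pmu_waveform else pmu_quadratic
  curves <- dplyr::bind_rows(
    build_rt_curves(cells, "relative"),
    build_rt_curves(cells, "absolute")
  )
  curves |>
    dplyr::group_by(.data$participant_id, .data$anchor, .data$phase) |>
    dplyr::group_modify(function(d, key) {
      if (!d$usable[1]) {
        return(tibble::tibble(pmu = NA_real_, method = method,
                              baseline = NA_real_, flag = "unusable"))
      }
      est(d$true_pct, d$logrt)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "anchor", "phase", "pmu", "method", "flag")
}
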