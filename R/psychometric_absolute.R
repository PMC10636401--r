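#' Fit the linear psychophysical function of absolute estimates
#'
#' Ordinary least squares of the per-cell mean absolute estimate on the true
#' feature percentage, for one participant x anchor. The PSE is the feature
#' percentage at which the fitted line predicts an estimate of 50%; the DL
#' is half the feature-percentage distance between fitted estimates of 25
#' and 75, i.e. `25 / slope`, so a shallower slope (poorer sensitivity)
#' yields a larger DL.
#'
#' @param cells Cell summaries for one participant x anchor: columns
#'   `true_pct` and `mean_estimate` (>= 2 non-missing levels).
#' @return One-row tibble: `intercept`, `slope`, `r_squared`, `pse`, `dl`,
#'   `n_points`, `valid_slope`; `pse`/`dl` are `NA` when the slope is not
#'   positive. Also carries `calibration_error`, the mean signed deviation
#'   of estimates from the true percentage (a bias diagnostic).
#' @export
fit_linear <- function(cells) {
  d <- cells[!is.na(cells$mean_estimate), c("true_pct", "mean_estimate")]
  if (length(unique(d$true_pct)) < 2) {
    stop("need >= 2 distinct true_pct levels with estimates to fit",
         call. = FALSE)
  }
  fit <- stats::lm(mean_estimate ~ true_pct, data = d)
  b <- unname(stats::coef(fit))
  ss_tot <- sum((d$mean_estimate - mean(d$mean_estimate))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  pd <- pse_dl_from_linear(b[1], b[2])
  tibble::tibble(
    intercept = b[1], slope = b[2], r_squared = r2,
    pse = pd$pse, dl = pd$dl, n_points = nrow(d),
    valid_slope = b[2] > 0,
    calibration_error = mean(d$mean_estimate - d$true_pct)
  )
}

#' PSE and DL from a fitted line
#'
#' @param intercept,slope Coefficients of the fitted line
#'   `estimate = intercept + slope * true_pct`.
#' @return Named list `pse = (50 - intercept) / slope`, `dl = 25 / slope`;
#'   both `NA` when `slope <= 0` (no rising function to invert).
#' @export
pse_dl_from_linear <- function(intercept, slope) {
  if (!is.finite(slope) || slope <= 0) {
    return(list(pse = NA_real_, dl = NA_real_))
  }
  list(pse = (50 - intercept) / slope, dl = 25 / slope)
}

#' Fit linear psychophysical functions for every participant x anchor
#'
#' @param cells Cell-summary tibble from [aggregate_cells()].
#' @return Tidy fit table, one row per participant x anchor, with attribute
#'   `mean_r_squared` over valid fits.
#' @export
fit_all_absolute <- function(cells) {
  fits <- cells |>
    dplyr::group_by(.data$participant_id, .data$anchor) |>
    dplyr::group_modify(function(d, key) {
      tryCatch(fit_linear(d),
               error = function(e) tibble::tibble(
                 intercept = NA_real_, slope = NA_real_, r_squared = NA_real_,
                 pse = NA_real_, dl = NA_real_, n_points = nrow(d),
                 valid_slope = FALSE, calibration_error = NA_real_))
    }) |>
    dplyr::ungroup()
  attr(fits, "mean_r_squared") <- mean(fits$r_squared[fits$valid_slope], na.rm = TRUE)
  fits
}
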