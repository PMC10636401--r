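#' Fit a logistic psychometric function to one participant x anchor
#'
#' Models the probability of a "larger" response as
#' `plogis((x - mu) / s)` in the true feature percentage `x`. The default
#' criterion is maximum likelihood on the per-cell binomial counts; a
#' least-squares criterion on the cell proportions is available as a
#' compatibility mode. The point of subjective equality is `pse = mu` and
#' the difference limen `dl = s * log(3)` (half the distance between the
#' 25% and 75% response points).
#'
#' @param cells Cell summaries for one participant x anchor: columns
#'   `true_pct`, `p_larger`, and `n_trials` (with `n_excluded_rel` honoured
#'   when present).
#' @param method `"mle"` (binomial likelihood, default) or `"ls"` (least
#'   squares on proportions).
#' @return One-row tibble: `mu`, `s`, `pse`, `dl`, `r_squared`, `converged`,
#'   `n_points`, `degenerate_code` (one of `"none"`, `"all_larger"`,
#'   `"all_smaller"`, `"non_monotone_flat"`).
#' @export
fit_logistic <- function(cells, method = c("mle", "ls")) {
  method <- match.arg(method)
  n_eff <- cells$n_trials -
    if ("n_excluded_rel" %in% names(cells)) cells$n_excluded_rel else 0
  ok <- !is.na(cells$p_larger) & n_eff > 0
  x <- cells$true_pct[ok]
  p <- cells$p_larger[ok]
  n <- n_eff[ok]
  out <- function(mu = NA_real_, s = NA_real_, r2 = NA_real_,
                  converged = FALSE, code = "none") {
    tibble::tibble(
      mu = mu, s = s, pse = mu, dl = s * log(3), r_squared = r2,
      converged = converged, n_points = length(x), degenerate_code = code
    )
  }
  if (length(unique(x)) < 3) {
    stop("need >= 3 distinct true_pct levels with data to fit", call. = FALSE)
  }
  if (all(p >= 1)) return(out(code = "all_larger"))
  if (all(p <= 0)) return(out(code = "all_smaller"))
  if (stats::sd(p) == 0) return(out(code = "non_monotone_flat"))

  # moment-based start: location from linear interpolation at p = 0.5,
  # scale from the spread of the central response range
  start_mu <- tryCatch(
    suppressWarnings(stats::approx(p, x, xout = 0.5, ties = mean)$y),
    error = function(e) NA_real_)
  if (!is.finite(start_mu)) start_mu <- stats::weighted.mean(x, n * p * (1 - p) + 1e-6)
  start_s <- max(diff(range(x)) / 8, 1)

  negll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    q <- stats::plogis((x - mu) / s)
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    -sum(n * (p * log(q) + (1 - p) * log(1 - q)))
  }
  ssq <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    sum((p - stats::plogis((x - mu) / s))^2)
  }
  obj <- if (method == "mle") negll else ssq
  fit <- stats::optim(c(start_mu, log(start_s)), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  # Nelder-Mead polish guards against BFGS stalling on flat likelihoods
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
  if (fit2$value < fit$value) fit <- fit2
  mu <- fit$par[1]; s <- exp(fit$par[2])
  # a scale beyond twice the whole response axis means the data carry no
  # usable slope information: treat as flat rather than report unstable params
  if (s > 200) return(out(code = "non_monotone_flat"))
  fitted <- stats::plogis((x - mu) / s)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- if (ss_tot > 0) 1 - sum((p - fitted)^2) / ss_tot else NA_real_
  out(mu, s, r2, converged = fit$convergence == 0)
}

#' PSE and DL from a logistic fit
#'
#' The PSE is the feature percentage at which "larger" and "smaller"
#' responses are equally likely (the logistic location); the DL is half the
#' distance between the 25% and 75% points, which for the logistic is
#' `s * log(3)` exactly (since `plogis(log 3) = 0.75`).
#'
#' @param fit One-row fit tibble from [fit_logistic()].
#' @return Named list `pse`, `dl`; `NA` for degenerate fits.
#' @export
pse_dl_from_fit <- function(fit) {
  if (!isTRUE(fit$converged) || fit$degenerate_code != "none") {
    return(list(pse = NA_real_, dl = NA_real_))
  }
  list(pse = fit$mu, dl = fit$s * log(3))
}

#' Fit logistic psychometric functions for every participant x anchor
#'
#' @param cells Cell-summary tibble from [aggregate_cells()].
#' @inheritParams fit_logistic
#' @return Tidy fit table, one row per participant x anchor, with an
#'   attribute `good_fit_fraction` giving the fraction of non-degenerate
#'   fits with `r_squared > 0.89`.
#' @export
fit_all_relative <- function(cells, method = c("mle", "ls")) {
  method <- match.arg(method)
  fits <- cells |>
    dplyr::group_by(.data$participant_id, .data$anchor) |>
    dplyr::group_modify(function(d, key) {
      tryCatch(fit_logistic(d, method = method),
               error = function(e) tibble::tibble(
                 mu = NA_real_, s = NA_real_, pse = NA_real_, dl = NA_real_,
                 r_squared = NA_real_, converged = FALSE,
                 n_points = nrow(d), degenerate_code = "none"))
    }) |>
    dplyr::ungroup()
  okr2 <- fits$r_squared[fits$converged & fits$degenerate_code == "none"]
  attr(fits, "good_fit_fraction") <- mean(okr2 > 0.89, na.rm = TRUE)
  fits
}
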