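#' Names of the generative observer parameters
#' @keywords internal
observer_param_names <- function() {
  c("mu0", "bias_slope", "sigma0", "sigma_slope",
    "est_intercept0", "est_anchor_weight", "est_slope0", "est_slope_mod",
    "est_noise_sd",
    "rt_base_rel", "rt_base_abs", "rt_amp_rel", "rt_amp_abs",
    "rt_width", "pmu_rel_slope", "pmu_abs_slope", "rt_noise_sd",
    "lapse")
}

#' Default population means for the synthetic cohort
#'
#' These define the simulated study conditions: an assimilative anchoring
#' bias on the relative-judgment PSE (`bias_slope` < 0), anchor-modulated
#' relative sensitivity (`sigma_slope` > 0), absolute estimates pulled toward
#' the anchor (`est_anchor_weight` > 0) with the shallowest stimulus slope at
#' moderate anchors (`est_slope_mod` > 0), and inverted-U log-RT curves whose
#' peak follows the anchor upward in the relative phase
#' (`pmu_rel_slope` > 0) and downward in the absolute phase
#' (`pmu_abs_slope` < 0).
#'
#' @return Named list of population means, one per observer parameter.
#' @export
default_population_means <- function() {
  list(
    mu0 = 50, bias_slope = -0.15,
    sigma0 = 6.5, sigma_slope = 0.05,
    est_intercept0 = 0, est_anchor_weight = 0.1,
    est_slope0 = 0.9, est_slope_mod = 0.2, est_noise_sd = 5,
    rt_base_rel = 6.3, rt_base_abs = 7.0,
    rt_amp_rel = 0.25, rt_amp_abs = 0.2,
    rt_width = 15, pmu_rel_slope = 0.3, pmu_abs_slope = -0.3,
    rt_noise_sd = 0.15,
    lapse = 0.02
  )
}

#' Default between-participant standard deviations
#' @return Named list of population SDs, one per observer parameter.
#' @export
default_population_sds <- function() {
  list(
    mu0 = 2.5, bias_slope = 0.05,
    sigma0 = 1.2, sigma_slope = 0.02,
    est_intercept0 = 3, est_anchor_weight = 0.04,
    est_slope0 = 0.08, est_slope_mod = 0.05, est_noise_sd = 1,
    rt_base_rel = 0.1, rt_base_abs = 0.1,
    rt_amp_rel = 0.05, rt_amp_abs = 0.05,
    rt_width = 2, pmu_rel_slope = 0.08, pmu_abs_slope = 0.08,
    rt_noise_sd = 0.03,
    lapse = 0.01
  )
}

#' Configure a synthetic observer cohort
#'
#' @param n_participants Number of simulated observers (study default 75).
#' @param n_exemplars Exemplars per design cell (study default 7, for 343
#'   trial sets per participant).
#' @param seed Integer seed; mandatory, drives every draw downstream.
#' @param means,sds Named lists overriding entries of
#'   [default_population_means()] / [default_population_sds()].
#' @param rt_log_base Log base used for RT transforms throughout the
#'   pipeline: `"e"` (natural, default) or `"10"`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 75, n_exemplars = 7, seed,
                          means = list(), sds = list(),
                          rt_log_base = c("e", "10")) {
  if (missing(seed)) stop("`seed` is required in a cohort config", call. = FALSE)
  rt_log_base <- match.arg(rt_log_base)
  stopifnot(n_participants >= 1, n_exemplars >= 1)
  m <- utils::modifyList(default_population_means(), means)
  s <- utils::modifyList(default_population_sds(), sds)
  bad <- setdiff(names(c(means, sds)), observer_param_names())
  if (length(bad) > 0) {
    stop("unknown observer parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(s) < 0)) stop("population SDs must be >= 0", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_exemplars = as.integer(n_exemplars),
         seed = as.integer(seed),
         means = m, sds = s, rt_log_base = rt_log_base),
    class = "cohort_config"
  )
}

validate_observer <- function(p) {
  a <- design_levels()
  if (any(p$sigma0 + p$sigma_slope * (a - 50) <= 0)) return("sigma_slope")
  if (p$est_slope0 - p$est_slope_mod <= 0) return("est_slope_mod")
  if (p$sigma0 <= 0) return("sigma0")
  if (p$est_noise_sd < 0) return("est_noise_sd")
  if (p$rt_noise_sd < 0) return("rt_noise_sd")
  if (p$rt_width <= 0) return("rt_width")
  if (p$rt_amp_rel < 0) return("rt_amp_rel")
  if (p$rt_amp_abs < 0) return("rt_amp_abs")
  if (p$lapse < 0 || p$lapse > 0.1) return("lapse")
  NULL
}

#' Draw one observer's parameters from the population
#'
#' Each parameter is drawn from a normal distribution with the configured
#' mean and SD; draws violating the parameter invariants (positive scales,
#' positive slopes at every anchor, lapse in \[0, 0.1\]) are rejected and
#' redrawn. Deterministic given `(cohort$seed, participant_index)`.
#'
#' @param cohort A [cohort_config()].
#' @param participant_index 1-based index, `<= n_participants`.
#' @return Named list of observer parameters (class `observer_params`).
#' @export
sample_observer <- function(cohort, participant_index) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (participant_index < 1 || participant_index > cohort$n_participants) {
    stop("participant_index out of range", call. = FALSE)
  }
  nm <- observer_param_names()
  mu <- unlist(cohort$means[nm])
  sd <- unlist(cohort$sds[nm])
  p <- NULL
  withr_seed(participant_seed(cohort$seed, participant_index, stream = 1L), {
    for (attempt in 1:200) {
      draw <- as.list(stats::rnorm(length(nm), mu, sd))
      names(draw) <- nm
      # directional truncations before invariant check
      draw$sigma0 <- max(draw$sigma0, 0.5)
      draw$rt_width <- max(draw$rt_width, 1)
      draw$est_noise_sd <- max(draw$est_noise_sd, 0)
      draw$rt_noise_sd <- max(draw$rt_noise_sd, 0)
      draw$rt_amp_rel <- max(draw$rt_amp_rel, 0)
      draw$rt_amp_abs <- max(draw$rt_amp_abs, 0)
      draw$est_slope_mod <- max(draw$est_slope_mod, 0)
      draw$pmu_rel_slope <- max(draw$pmu_rel_slope, 0)
      draw$pmu_abs_slope <- min(draw$pmu_abs_slope, 0)
      draw$lapse <- min(max(draw$lapse, 0), 0.1)
      if (is.null(validate_observer(draw))) {
        p <- draw
        break
      }
    }
  })
  if (is.null(p)) {
    stop("could not draw valid observer parameters (participant ",
         participant_index, "); offending parameter: ",
         validate_observer(draw), call. = FALSE)
  }
  structure(p, class = "observer_params")
}

#' Probability of a "larger" relative judgment
#'
#' The generative psychometric function: a two-parameter logistic in the true
#' feature percentage whose location shifts with the anchor (assimilative
#' bias) and whose scale grows with the anchor (sensitivity loss), mixed with
#' a small stimulus-independent lapse.
#'
#' `p = lapse/2 + (1 - lapse) * plogis((x - mu(a)) / sigma(a))` with
#' `mu(a) = mu0 + bias_slope * (a - 50)` and
#' `sigma(a) = sigma0 + sigma_slope * (a - 50)`.
#'
#' @param obs Observer parameters from [sample_observer()].
#' @param anchor,true_pct Percent values in \[0, 100\]; vectorized.
#' @return Probability vector.
#' @export
relative_response_prob <- function(obs, anchor, true_pct) {
  stopifnot(all(anchor >= 0 & anchor <= 100), all(true_pct >= 0 & true_pct <= 100))
  mu <- obs$mu0 + obs$bias_slope * (anchor - 50)
  sigma <- obs$sigma0 + obs$sigma_slope * (anchor - 50)
  if (any(sigma <= 0)) {
    stop("logistic scale sigma(a) <= 0 for some anchor", call. = FALSE)
  }
  obs$lapse / 2 + (1 - obs$lapse) * stats::plogis((true_pct - mu) / sigma)
}

# stimulus slope of the absolute-estimate line at anchor a; shallowest at
# moderate anchors (a = 50), recovering est_slope0 at the extremes (|a-50|=30)
estimate_slope <- function(obs, anchor) {
  obs$est_slope0 - obs$est_slope_mod * (1 - abs(anchor - 50) / 30)
}

#' Simulate an absolute percentage estimate
#'
#' Linear generative model: the estimate regresses on the true percentage
#' with an anchor-dependent slope and is pulled toward the anchor through
#' `est_anchor_weight`; Gaussian response noise; clipped to the 0-100
#' response scale.
#'
#' @inheritParams relative_response_prob
#' @param noise_sd Override for the observer's `est_noise_sd` (used to
#'   obtain the noise-free mean response).
#' @return Estimate vector in \[0, 100\].
#' @export
absolute_estimate <- function(obs, anchor, true_pct, noise_sd = obs$est_noise_sd) {
  stopifnot(all(anchor >= 0 & anchor <= 100), all(true_pct >= 0 & true_pct <= 100))
  sl <- estimate_slope(obs, anchor)
  if (any(sl <= 0)) stop("estimate slope <= 0 for some anchor", call. = FALSE)
  n <- max(length(anchor), length(true_pct))
  est <- 50 + obs$est_intercept0 + obs$est_anchor_weight * (anchor - 50) +
    sl * (true_pct - 50) +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  pmin(pmax(est, 0), 100)
}

#' Simulate the pair of log reaction times for one trial
#'
#' Each phase's log RT is an inverted-U (Gaussian bump) in the true feature
#' percentage, peaking at the phase's point of maximal uncertainty:
#' `P_rel(a) = 50 + pmu_rel_slope * (a - 50)` for the relative judgment and
#' `P_abs(a) = 50 + pmu_abs_slope * (a - 50)` for the absolute estimate,
#' plus Gaussian noise. Values are returned in the requested log base.
#'
#' @inheritParams relative_response_prob
#' @param noise_sd Override for `rt_noise_sd`.
#' @param log_base `"e"` or `"10"`.
#' @return List with components `logrt_rel` and `logrt_abs`.
#' @export
simulate_rts <- function(obs, anchor, true_pct, noise_sd = obs$rt_noise_sd,
                         log_base = "e") {
  n <- max(length(anchor), length(true_pct))
  bump <- function(base, amp, peak) {
    base + amp * exp(-(true_pct - peak)^2 / (2 * obs$rt_width^2)) +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  }
  p_rel <- 50 + obs$pmu_rel_slope * (anchor - 50)
  p_abs <- 50 + obs$pmu_abs_slope * (anchor - 50)
  out <- list(
    logrt_rel = bump(obs$rt_base_rel, obs$rt_amp_rel, p_rel),
    logrt_abs = bump(obs$rt_base_abs, obs$rt_amp_abs, p_abs)
  )
  if (identical(log_base, "10")) out <- lapply(out, function(x) x / log(10))
  out
}

#' Simulate a full two-phase anchoring experiment
#'
#' Generates each participant's 7 x 7 x `n_exemplars` design, draws observer
#' parameters from the population, and simulates every trial: a Bernoulli
#' "larger" response from the generative psychometric function, an absolute
#' estimate from the linear model, and the two log RTs (converted to
#' milliseconds on the raw scale). Fully reproducible from the config seed.
#'
#' @param cohort A [cohort_config()].
#' @return List with `trials` (one row per trial) and `params` (the true
#'   observer parameters, one row per participant, for recovery testing).
#' @examples
#' sim <- simulate_experiment(cohort_config(n_participants = 2, seed = 1))
#' nrow(sim$trials) # 2 * 343
#' @export
simulate_experiment <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_config"))
  one <- function(i) {
    obs <- sample_observer(cohort, i)
    design <- make_design(cohort$n_exemplars,
                          participant_seed(cohort$seed, i, stream = 2L))
    trial_seed <- participant_seed(cohort$seed, i, stream = 3L)
    withr_seed(trial_seed, {
      p <- relative_response_prob(obs, design$anchor, design$true_pct)
      resp <- stats::rbinom(nrow(design), 1L, p)
      est <- absolute_estimate(obs, design$anchor, design$true_pct)
      rts <- simulate_rts(obs, design$anchor, design$true_pct,
                          log_base = cohort$rt_log_base)
    })
    to_ms <- if (cohort$rt_log_base == "10") function(x) 10^x else exp
    trials <- design |>
      dplyr::mutate(
        participant_id = sprintf("P%03d", i), .before = 1
      ) |>
      dplyr::mutate(
        relative_response = resp,
        rt_relative_ms = to_ms(rts$logrt_rel),
        absolute_estimate = est,
        rt_absolute_ms = to_ms(rts$logrt_abs)
      )
    list(trials = trials,
         params = tibble::as_tibble(c(list(participant_id = sprintf("P%03d", i)),
                                      unclass(obs))))
  }
  sims <- lapply(seq_len(cohort$n_participants), one)
  list(
    trials = dplyr::bind_rows(lapply(sims, `[[`, "trials")),
    params = dplyr::bind_rows(lapply(sims, `[[`, "params"))
  )
}

#' Noise-free cell summaries for a cohort (infinite-trials limit)
#'
#' Computes, for every sampled observer, the exact per-cell quantities the
#' trial simulation converges to as the number of trials per cell grows:
#' the generative "larger" probability, the noise-free mean estimate, and
#' the noise-free log RTs. Useful for checking the directional orderings
#' that hold exactly in the noise-free limit, and for fitter
#' self-consistency tests.
#'
#' @param cohort A [cohort_config()].
#' @return Cell-summary tibble in the [aggregate_cells()] layout, plus the
#'   true parameters in attribute `"params"`.
#' @export
cell_summaries_exact <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_config"))
  lv <- design_levels()
  grid <- tidyr::expand_grid(anchor = lv, true_pct = lv)
  one <- function(i) {
    obs <- sample_observer(cohort, i)
    rts <- simulate_rts(obs, grid$anchor, grid$true_pct, noise_sd = 0,
                        log_base = cohort$rt_log_base)
    cells <- grid |>
      dplyr::mutate(
        participant_id = sprintf("P%03d", i), .before = 1
      ) |>
      dplyr::mutate(
        n_trials = cohort$n_exemplars,
        n_excluded_rel = 0L, n_excluded_abs = 0L,
        p_larger = relative_response_prob(obs, .data$anchor, .data$true_pct),
        mean_estimate = absolute_estimate(obs, .data$anchor, .data$true_pct,
                                          noise_sd = 0),
        mean_logrt_rel = rts$logrt_rel,
        mean_logrt_abs = rts$logrt_abs
      )
    list(cells = cells,
         params = tibble::as_tibble(c(list(participant_id = sprintf("P%03d", i)),
                                      unclass(obs))))
  }
  res <- lapply(seq_len(cohort$n_participants), one)
  out <- dplyr::bind_rows(lapply(res, `[[`, "cells"))
  attr(out, "params") <- dplyr::bind_rows(lapply(res, `[[`, "params"))
  out
}
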