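test_that("make_design crosses anchors, percentages and exemplars in balance", {
  d <- make_design(n_exemplars = 7, seed = 1)
  expect_equal(nrow(d), 343)
  counts <- dplyr::count(d, anchor, true_pct)
  expect_equal(nrow(counts), 49)
  expect_true(all(counts$n == 7))
  expect_equal(anyDuplicated(d$category_label), 0L)

  d1 <- make_design(n_exemplars = 1, seed = 3)
  expect_equal(nrow(d1), 49)
  expect_error(make_design(0, seed = 1), "n_exemplars")
})

test_that("make_design is deterministic in the seed and varies across seeds", {
  expect_identical(make_design(7, seed = 5), make_design(7, seed = 5))
  a <- make_design(7, seed = 5)
  b <- make_design(7, seed = 6)
  expect_true(any(a$anchor != b$anchor | a$true_pct != b$true_pct |
                    a$category_label != b$category_label))
})

test_that("sample_observer honours degenerate and seeded-draw contracts", {
  zero_sds <- lapply(default_population_sds(), function(x) 0)
  co <- cohort_config(n_participants = 3, seed = 7, sds = zero_sds)
  o1 <- sample_observer(co, 1)
  o2 <- sample_observer(co, 2)
  expect_equal(unclass(o1)[observer_param_names()],
               default_population_means()[observer_param_names()])
  expect_equal(unclass(o1), unclass(o2))

  co2 <- cohort_config(n_participants = 5, seed = 11)
  expect_identical(sample_observer(co2, 3), sample_observer(co2, 3))
  expect_error(sample_observer(co2, 6), "out of range")
})

test_that("sampled parameters follow the stated population distribution", {
  co <- cohort_config(n_participants = 1000, seed = 13,
                      means = list(mu0 = 50), sds = list(mu0 = 4))
  draws <- vapply(1:1000, function(i) sample_observer(co, i)$mu0, numeric(1))
  se <- 4 / sqrt(1000)
  expect_lt(abs(mean(draws) - 50), 3 * se)
})

test_that("relative_response_prob matches the logistic closed forms", {
  obs <- mean_observer(lapse = 0, mu0 = 50, bias_slope = -0.2,
                       sigma0 = 8, sigma_slope = 0)
  # midpoint and the 75% point of the logistic
  expect_equal(relative_response_prob(obs, 50, 50), 0.5)
  expect_equal(relative_response_prob(obs, 50, 50 + 8 * log(3)), 0.75)
  # assimilation: same stimulus, higher anchor, more "larger" responses
  expect_gt(relative_response_prob(obs, 80, 50),
            relative_response_prob(obs, 20, 50))
  # monotone nondecreasing in the true percentage
  p <- relative_response_prob(obs, 40, design_x)
  expect_true(all(diff(p) >= 0))
  bad <- mean_observer(sigma0 = 1, sigma_slope = -0.2)
  expect_error(relative_response_prob(bad, 80, 50), "sigma")
})

test_that("absolute_estimate follows the anchor-weighted linear model", {
  ident <- mean_observer(est_noise_sd = 0, est_slope_mod = 0,
                         est_anchor_weight = 0, est_intercept0 = 0,
                         est_slope0 = 1)
  expect_equal(absolute_estimate(ident, 30, design_x), design_x)

  pulled <- mean_observer(est_noise_sd = 0, est_anchor_weight = 0.1)
  for (x in design_x) {
    expect_gt(absolute_estimate(pulled, 80, x), absolute_estimate(pulled, 20, x))
  }
  # slope is shallowest at the moderate anchor, recovering est_slope0 at the extremes
  mod <- mean_observer(est_slope_mod = 0.2, est_slope0 = 0.9)
  slopes <- vapply(c(20, 50, 80), function(a) {
    (absolute_estimate(mod, a, 60, noise_sd = 0) -
       absolute_estimate(mod, a, 40, noise_sd = 0)) / 20
  }, numeric(1))
  expect_equal(slopes[1], 0.9)
  expect_equal(slopes[3], 0.9)
  expect_equal(slopes[2], 0.7)
  expect_lt(slopes[2], slopes[1])
})

test_that("simulate_rts produces anchor-dependent inverted-U log-RT curves", {
  flat <- mean_observer(rt_amp_rel = 0, rt_noise_sd = 0)
  rts <- simulate_rts(flat, 50, design_x, noise_sd = 0)
  expect_equal(diff(range(rts$logrt_rel)), 0)

  centred <- mean_observer(pmu_rel_slope = 0, rt_noise_sd = 0)
  y <- simulate_rts(centred, 80, design_x, noise_sd = 0)$logrt_rel
  expect_equal(design_x[which.max(y)], 50)

  moving <- mean_observer(pmu_rel_slope = 0.3, rt_noise_sd = 0)
  y20 <- simulate_rts(moving, 20, design_x, noise_sd = 0)$logrt_rel
  y80 <- simulate_rts(moving, 80, design_x, noise_sd = 0)$logrt_rel
  expect_gt(design_x[which.max(y80)], design_x[which.max(y20)])

  # base-10 output is the natural-log curve rescaled
  e <- simulate_rts(centred, 50, design_x, noise_sd = 0, log_base = "e")
  b10 <- simulate_rts(centred, 50, design_x, noise_sd = 0, log_base = "10")
  expect_equal(b10$logrt_rel, e$logrt_rel / log(10))
})

test_that("simulate_experiment delivers the full balanced trial table, reproducibly", {
  co <- cohort_config(n_participants = 2, seed = 21)
  sim <- simulate_experiment(co)
  expect_equal(nrow(sim$trials), 2 * 343)
  expect_equal(nrow(sim$params), 2)
  counts <- dplyr::count(sim$trials, participant_id, anchor, true_pct)
  expect_true(all(counts$n == co$n_exemplars))

  sim2 <- simulate_experiment(co)
  expect_identical(sim$trials, sim2$trials)

  tiny <- simulate_experiment(cohort_config(n_participants = 1, n_exemplars = 1,
                                            seed = 2))
  expect_equal(nrow(tiny$trials), 49)
})

test_that("simulated response proportions converge to the generative probabilities", {
  zero_sds <- lapply(default_population_sds(), function(x) 0)
  co <- cohort_config(n_participants = 1, n_exemplars = 10000, seed = 31,
                      means = list(lapse = 0, est_noise_sd = 0, rt_noise_sd = 0),
                      sds = zero_sds)
  sim <- simulate_experiment(co)
  obs <- sample_observer(co, 1)
  props <- sim$trials |>
    dplyr::group_by(anchor, true_pct) |>
    dplyr::summarise(p = mean(relative_response), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(p_true = relative_response_prob(obs, anchor, true_pct))
  se <- sqrt(props$p_true * (1 - props$p_true) / props$n)
  expect_true(all(abs(props$p - props$p_true) <= 3 * pmax(se, 1e-12) + 1e-12))
})

test_that("noise-free limit has the generative directional ground truth", {
  cells <- cell_summaries_exact(cohort_config(n_participants = 20, seed = 41))
  truth <- attr(cells, "params")
  a <- design_x
  pse_true <- vapply(a, function(aa) mean(truth$mu0 + truth$bias_slope * (aa - 50)),
                     numeric(1))
  dl_true <- vapply(a, function(aa) {
    mean((truth$sigma0 + truth$sigma_slope * (aa - 50)) * log(3))
  }, numeric(1))
  expect_true(all(diff(pse_true) < 0))
  expect_true(all(diff(dl_true) > 0))
  p_rel <- vapply(a, function(aa) mean(50 + truth$pmu_rel_slope * (aa - 50)),
                  numeric(1))
  p_abs <- vapply(a, function(aa) mean(50 + truth$pmu_abs_slope * (aa - 50)),
                  numeric(1))
  expect_true(all(diff(p_rel) > 0))
  expect_true(all(diff(p_abs) < 0))
})
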