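test_that("trial tables round-trip through CSV", {
  sim <- simulate_experiment(cohort_config(n_participants = 1, n_exemplars = 2,
                                           seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$trials[names(back)]))
  expect_equal(length(unique(back$anchor)), 7)
})

test_that("read_trials reports schema and validation problems by name", {
  sim <- simulate_experiment(cohort_config(n_participants = 1, n_exemplars = 1,
                                           seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(sim$trials, -rt_relative_ms), path)
  suppressWarnings(expect_error(read_trials(path), "rt_relative_ms"))

  bad <- sim$trials
  bad$anchor[3] <- 35
  write_trials(bad, path)
  expect_error(read_trials(path), "grid")
  expect_warning(read_trials(path, strict_grid = FALSE), "grid")
})

test_that("SD-criterion exclusion flags gross outliers and nothing else", {
  rts <- c(rep(500, 100), 50000)
  tr <- rt_trials(rts)
  res <- exclude_rt_outliers(tr)
  expect_equal(which(res$trials$exclude_rel), 101L)
  expect_equal(sum(res$trials$exclude_abs), 1L)

  same <- exclude_rt_outliers(rt_trials(rep(400, 50)))
  expect_equal(sum(same$trials$exclude_rel), 0L)

  rep_rel <- res$report[res$report$phase == "relative", ]
  expect_equal(rep_rel$n_in, 101L)
  expect_equal(rep_rel$n_excluded, 1L)
})

test_that("exclusion fraction on Gaussian RTs matches the normal tail rate", {
  set.seed(91)
  rts <- rnorm(10000, 800, 100)
  res <- exclude_rt_outliers(rt_trials(rts), threshold_sd = 3)
  frac <- mean(res$trials$exclude_rel)
  expected <- 2 * pnorm(-3)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("aggregation counts per phase independently and conserves trials", {
  sim <- simulate_experiment(cohort_config(n_participants = 1, seed = 8))
  tr <- sim$trials
  # force one relative-phase exclusion in a known cell
  cell_rows <- which(tr$anchor == 50 & tr$true_pct == 50)
  tr$rt_relative_ms[cell_rows[1]] <- 1e6
  res <- exclude_rt_outliers(tr)
  cells <- aggregate_cells(res$trials)
  expect_equal(nrow(cells), 49)
  cell <- cells[cells$anchor == 50 & cells$true_pct == 50, ]
  expect_equal(cell$n_excluded_rel, 1L)
  expect_equal(cell$n_excluded_abs, 0L)
  # p_larger over the 6 retained relative trials, estimate over all 7
  kept <- res$trials[cell_rows, ]
  expect_equal(cell$p_larger,
               mean(kept$relative_response[!kept$exclude_rel]))
  expect_equal(cell$mean_estimate, mean(kept$absolute_estimate))

  # conservation: retained + excluded = total, per phase
  expect_equal(sum(cells$n_trials - cells$n_excluded_rel) +
                 sum(res$report$n_excluded[res$report$phase == "relative"]),
               nrow(tr))
  expect_equal(sum(cells$n_trials - cells$n_excluded_abs) +
                 sum(res$report$n_excluded[res$report$phase == "absolute"]),
               nrow(tr))
})

test_that("cell proportions count correctly and ignore input row order", {
  tr <- rt_trials(rep(500, 7))
  tr$anchor <- 40; tr$true_pct <- 60
  tr$relative_response <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L)
  cells <- aggregate_cells(tr)
  expect_equal(cells$p_larger, 5 / 7)

  sim <- simulate_experiment(cohort_config(n_participants = 2, n_exemplars = 3,
                                           seed = 9))
  shuffled <- sim$trials[sample(nrow(sim$trials)), ]
  expect_equal(
    dplyr::arrange(aggregate_cells(sim$trials), participant_id, anchor, true_pct),
    dplyr::arrange(aggregate_cells(shuffled), participant_id, anchor, true_pct)
  )
})

test_that("log base configures the aggregated RT means", {
  tr <- rt_trials(rep(c(400, 800), 4)[1:7])
  tr$anchor <- 20; tr$true_pct <- 20
  ce <- aggregate_cells(tr, log_base = "e")
  c10 <- aggregate_cells(tr, log_base = "10")
  expect_equal(ce$mean_logrt_rel, mean(log(tr$rt_relative_ms)))
  expect_equal(c10$mean_logrt_rel, mean(log10(tr$rt_relative_ms)))
})
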