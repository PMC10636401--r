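toy_twoway <- function(n = 3, nA = 2, nB = 2, seed = 61, sd = 1,
                       shift_A = 0) {
  set.seed(seed)
  d <- expand.grid(pid = sprintf("s%d", 1:n),
                   A = sprintf("a%d", 1:nA),
                   B = sprintf("b%d", 1:nB))
  d$y <- rnorm(nrow(d), 0, sd) + shift_A * as.integer(factor(d$A))
  d
}

test_that("two-way RM-ANOVA equals the explicit sums-of-squares oracle", {
  for (cfg in list(c(3, 2, 2), c(5, 3, 3), c(4, 3, 2))) {
    d <- toy_twoway(cfg[1], cfg[2], cfg[3], seed = sum(cfg))
    res <- rm_anova_twoway(d, "y", factors = c("A", "B"), participant = "pid")
    or <- ss_oracle_twoway(d)
    for (pair in list(c("A", "A"), c("B", "B"), c("A:B", "AB"))) {
      r <- res[res$effect == pair[1], ]
      o <- or[[pair[2]]]
      expect_lt(abs(r$ss_effect - o$ss), 1e-10)
      expect_lt(abs(r$ss_error - o$ss_err), 1e-10)
      expect_equal(r$df_effect, o$df)
      expect_equal(r$df_error, o$df_err)
      expect_lt(abs(r$F - (o$ss / o$df) / (o$ss_err / o$df_err)), 1e-10)
      expect_lt(abs(r$partial_eta_sq - o$ss / (o$ss + o$ss_err)), 1e-12)
    }
    # SS conservation over the full decomposition
    parts <- or$ss_subj + or$A$ss + or$B$ss + or$AB$ss +
      or$A$ss_err + or$B$ss_err + or$AB$ss_err
    expect_lt(abs(parts - or$ss_total), 1e-9)
  }
})

test_that("one-way RM-ANOVA equals the oracle and reports the familiar dfs", {
  set.seed(67)
  d <- expand.grid(pid = sprintf("s%d", 1:4), A = sprintf("a%d", 1:3))
  d$y <- rnorm(nrow(d))
  res <- rm_anova_oneway(d, "y", factor_col = "A", participant = "pid")
  o <- ss_oracle_oneway(d)
  expect_lt(abs(res$ss_effect - o$ss), 1e-10)
  expect_lt(abs(res$F - (o$ss / o$df) / (o$ss_err / o$df_err)), 1e-10)
  expect_lt(abs(res$partial_eta_sq - o$ss / (o$ss + o$ss_err)), 1e-12)

  # 7-level factor, n participants -> df (6, 6(n-1))
  d7 <- expand.grid(pid = sprintf("s%d", 1:75), A = sprintf("a%d", 1:7))
  set.seed(68); d7$y <- rnorm(nrow(d7))
  r7 <- rm_anova_oneway(d7, "y", factor_col = "A", participant = "pid")
  expect_equal(r7$df_effect, 6)
  expect_equal(r7$df_error, 444)
})

test_that("degenerate inputs are guarded", {
  d <- toy_twoway(3, 2, 2)
  d$y <- 1
  res <- rm_anova_twoway(d, "y", factors = c("A", "B"), participant = "pid")
  expect_true(all(res$F == 0))
  expect_true(all(res$zero_ss))
  expect_true(all(res$partial_eta_sq == 0))

  # missing cell: error by default, listwise drop on request
  d2 <- toy_twoway(3, 2, 2)[-1, ]
  expect_error(rm_anova_twoway(d2, "y", factors = c("A", "B"),
                               participant = "pid"), "missing cells")
  res2 <- rm_anova_twoway(d2, "y", factors = c("A", "B"), participant = "pid",
                          on_incomplete = "drop")
  expect_equal(res2$df_error[1], 1)  # 2 participants remain
  one <- data.frame(pid = "s1", A = c("a1", "a2"), y = c(1, 2))
  expect_error(rm_anova_oneway(one, "y", factor_col = "A", participant = "pid"),
               "2 participants")
})

test_that("anchor main effect is detected under an injected additive shift", {
  set.seed(71)
  d <- expand.grid(pid = sprintf("s%02d", 1:75),
                   anchor = design_x, true_pct = design_x)
  d$y <- rnorm(nrow(d), 0, 1) + 0.02 * (d$anchor - 50)
  res <- rm_anova_twoway(d, "y", participant = "pid")
  expect_lt(res$p[res$effect == "anchor"], 0.001)
})

test_that("linear contrast scores follow the stated arithmetic", {
  d <- expand.grid(pid = sprintf("s%d", 1:4), anchor = design_x)
  d$y <- 1.5
  res <- linear_contrast(d, "y", participant = "pid")
  expect_equal(res$mean_score, 0)
  expect_true(all(unlist(res$scores) == 0))

  d$y <- d$anchor
  res2 <- linear_contrast(d, "y", participant = "pid")
  expect_equal(res2$mean_score, 280)

  # linearity: contrast(a*y + b) = a * contrast(y)
  set.seed(73)
  d$y <- rnorm(nrow(d))
  s0 <- linear_contrast(d, "y", participant = "pid")$mean_score
  d$y2 <- 2.5 * d$y + 7
  expect_equal(linear_contrast(d, "y2", participant = "pid")$mean_score,
               2.5 * s0, tolerance = 1e-12)
})

test_that("stratified contrast returns one profile row per stimulus level", {
  cells <- cell_summaries_exact(cohort_config(n_participants = 8, seed = 79))
  res <- linear_contrast(cells, "p_larger", by = "true_pct")
  expect_equal(nrow(res), 7)
  expect_equal(res$true_pct, design_x)
  expect_true(all(res$n == 8))
  expect_true("p_holm" %in% names(res))
  # anchoring magnitude largest where the stimulus is most ambiguous
  expect_equal(res$true_pct[which.max(abs(res$mean_score))], 50)
})
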