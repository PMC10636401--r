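# Shared fixture builders. All randomness is seeded locally.

design_x <- seq(20, 80, 10)

# cell summaries following an exact logistic curve (no sampling noise)
logistic_cells <- function(mu, s, n_trials = 7, lapse = 0) {
  tibble::tibble(
    true_pct = design_x,
    p_larger = lapse / 2 + (1 - lapse) * plogis((design_x - mu) / s),
    n_trials = n_trials
  )
}

# cell summaries on an exact line
linear_cells <- function(intercept, slope) {
  tibble::tibble(
    true_pct = design_x,
    mean_estimate = intercept + slope * design_x
  )
}

# a deterministic "observer" built directly from the population means
mean_observer <- function(...) {
  p <- utils::modifyList(default_population_means(), list(...))
  structure(p, class = "observer_params")
}

# small trial table with hand-controlled RTs (other fields filled minimally)
rt_trials <- function(rt_rel, rt_abs = rt_rel, participant_id = "P001") {
  n <- length(rt_rel)
  tibble::tibble(
    participant_id = participant_id,
    set_index = seq_len(n),
    anchor = rep_len(design_x, n),
    true_pct = rep_len(design_x, n),
    stimulus_class = "discrete",
    category_label = sprintf("cat_%d", seq_len(n)),
    exemplar_index = 1L,
    relative_response = rep_len(c(0L, 1L), n),
    rt_relative_ms = rt_rel,
    absolute_estimate = 50,
    rt_absolute_ms = rt_abs
  )
}

# explicit two-way within-subject sums-of-squares decomposition, written
# directly from the cell-mean definitions (independent of stats::aov)
ss_oracle_twoway <- function(d, pid = "pid", A = "A", B = "B", y = "y") {
  d <- data.frame(pid = d[[pid]], A = d[[A]], B = d[[B]], y = d[[y]])
  m <- mean(d$y)
  nA <- length(unique(d$A)); nB <- length(unique(d$B))
  n <- length(unique(d$pid))
  mi <- tapply(d$y, d$pid, mean)
  ma <- tapply(d$y, d$A, mean)
  mb <- tapply(d$y, d$B, mean)
  mia <- tapply(d$y, list(d$pid, d$A), mean)
  mib <- tapply(d$y, list(d$pid, d$B), mean)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- n * nB * sum((ma - m)^2)
  ss_b <- n * nA * sum((mb - m)^2)
  ss_ab <- n * sum((sweep(sweep(mab, 1, ma), 2, mb) + m)^2)
  ss_err_a <- nB * sum((sweep(sweep(mia, 1, mi), 2, ma) + m)^2)
  ss_err_b <- nA * sum((sweep(sweep(mib, 1, mi), 2, mb) + m)^2)
  resid <- d$y
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    resid[i] <- r$y -
      mia[as.character(r$pid), as.character(r$A)] -
      mib[as.character(r$pid), as.character(r$B)] -
      mab[as.character(r$A), as.character(r$B)] +
      mi[as.character(r$pid)] + ma[as.character(r$A)] + mb[as.character(r$B)] - m
  }
  ss_err_ab <- sum(resid^2)
  list(
    A = list(ss = ss_a, ss_err = ss_err_a,
             df = nA - 1, df_err = (nA - 1) * (n - 1)),
    B = list(ss = ss_b, ss_err = ss_err_b,
             df = nB - 1, df_err = (nB - 1) * (n - 1)),
    AB = list(ss = ss_ab, ss_err = ss_err_ab,
              df = (nA - 1) * (nB - 1), df_err = (nA - 1) * (nB - 1) * (n - 1)),
    ss_subj = nA * nB * sum((mi - m)^2),
    ss_total = sum((d$y - m)^2)
  )
}

# one-way within-subject sums of squares, same style
ss_oracle_oneway <- function(d, pid = "pid", A = "A", y = "y") {
  d <- data.frame(pid = d[[pid]], A = d[[A]], y = d[[y]])
  m <- mean(d$y)
  nA <- length(unique(d$A)); n <- length(unique(d$pid))
  mi <- tapply(d$y, d$pid, mean)
  ma <- tapply(d$y, d$A, mean)
  mia <- tapply(d$y, list(d$pid, d$A), mean)
  ss_a <- n * sum((ma - m)^2)
  ss_err <- sum((sweep(sweep(mia, 1, mi), 2, ma) + m)^2)
  list(ss = ss_a, ss_err = ss_err, df = nA - 1, df_err = (nA - 1) * (n - 1))
}

# per-anchor means of a fit-table column, anchors ascending
anchor_means <- function(df, col) {
  df <- df[!is.na(df[[col]]), ]
  out <- tapply(df[[col]], df$anchor, mean)
  as.numeric(out[order(as.numeric(names(out)))])
}
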