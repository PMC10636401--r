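#!/usr/bin/env Rscript
# Stage 3: psychophysical function fits.
#
# Relative judgments: per participant x anchor, a two-parameter logistic of
# p("larger") against the true feature percentage, giving PSE (bias) and
# DL = s*ln(3) (sensitivity). Absolute estimates: per participant x anchor,
# an OLS line of the mean estimate against the true percentage, giving
# PSE = (50 - intercept)/slope and DL = 25/slope.

suppressMessages({library(anchordecomp); library(dplyr)})

cells <- readr::read_csv("results/cell_summaries.csv", show_col_types = FALSE)

fits_rel <- fit_all_relative(cells, method = "mle")
fits_abs <- fit_all_absolute(cells)
readr::write_csv(fits_rel, "results/fits_relative.csv")
readr::write_csv(fits_abs, "results/fits_absolute.csv")

message(sprintf("Logistic fits: %d; fraction with R2 > .89: %.2f",
                nrow(fits_rel), attr(fits_rel, "good_fit_fraction")))
message(sprintf("Linear fits: %d; mean R2: %.3f",
                nrow(fits_abs), attr(fits_abs, "mean_r_squared")))

by_anchor <- function(df, col) {
  df |> filter(!is.na(.data[[col]])) |>
    group_by(anchor) |> summarise(m = mean(.data[[col]])) |> pull(m)
}
message("Mean relative PSE by anchor (20..80): ",
        paste(sprintf("%.1f", by_anchor(fits_rel, "pse")), collapse = " "))
message("Mean relative DL  by anchor (20..80): ",
        paste(sprintf("%.1f", by_anchor(fits_rel, "dl")), collapse = " "))
message("Mean absolute PSE by anchor (20..80): ",
        paste(sprintf("%.1f", by_anchor(fits_abs, "pse")), collapse = " "))
message("Mean absolute DL  by anchor (20..80): ",
        paste(sprintf("%.1f", by_anchor(fits_abs, "dl")), collapse = " "))

# recovery against the generative parameters written in stage 1
truth <- readr::read_csv("results/observer_params_true.csv",
                         show_col_types = FALSE)
ok <- fits_rel |> filter(degenerate_code == "none", converged)
slope <- unname(coef(lm(pse ~ anchor, ok))[2])
message(sprintf("Fitted PSE-vs-anchor slope %.3f (generative mean %.3f)",
                slope, mean(truth$bias_slope)))
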