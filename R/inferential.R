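#' Two-way repeated-measures ANOVA with partial eta squared
#'
#' Classical univariate within-subject decomposition for a fully crossed,
#' balanced participant x factor A x factor B design: each effect is tested
#' against its participant-by-effect interaction error term. Reports
#' uncorrected F, dfs and p (the headline output) together with the
#' Greenhouse-Geisser epsilon and corrected p for each effect, and the
#' partial eta squared `SS_effect / (SS_effect + SS_error)`.
#'
#' @param df Long tibble with one value per participant x cell.
#' @param value Name of the value column.
#' @param factors Character vector naming the two within-subject factor
#'   columns.
#' @param participant Name of the participant id column.
#' @param on_incomplete `"error"` (default) or `"drop"` — drop participants
#'   with any missing cell listwise.
#' @return Tibble with one row per effect (A, B, A:B): `effect`,
#'   `df_effect`, `df_error`, `ss_effect`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq`, `gg_epsilon`, `p_gg`, `zero_ss`.
#' @export
rm_anova_twoway <- function(df, value, factors = c("anchor", "true_pct"),
                            participant = "participant_id",
                            on_incomplete = c("error", "drop")) {
  on_incomplete <- match.arg(on_incomplete)
  stopifnot(length(factors) == 2)
  d <- prepare_rm_data(df, value, factors, participant, on_incomplete)
  a_lv <- levels(d$.A); b_lv <- levels(d$.B)
  n <- nlevels(d$.pid)
  if (n < 2) stop("need >= 2 participants for a repeated-measures ANOVA",
                  call. = FALSE)

  fit <- stats::aov(.y ~ .A * .B + Error(.pid / (.A * .B)), data = d)
  tab <- extract_aov_effects(fit,
                             c(".A" = factors[1], ".B" = factors[2],
                               ".A:.B" = paste(factors, collapse = ":")))

  # Greenhouse-Geisser epsilon from the participant-level cell covariance
  wide <- matrix(d$.y[order(d$.pid, d$.A, d$.B)],
                 nrow = n, byrow = TRUE)  # columns ordered A fastest-last: (A,B)
  ca <- orthonormal_contrasts(length(a_lv))
  cb <- orthonormal_contrasts(length(b_lv))
  ia <- diag(length(a_lv)); ib <- diag(length(b_lv))
  eff_c <- list(
    kronecker(ca, matrix(1 / length(b_lv), 1, length(b_lv))),
    kronecker(matrix(1 / length(a_lv), 1, length(a_lv)), cb),
    kronecker(ca, cb)
  )
  tab$gg_epsilon <- vapply(eff_c, gg_epsilon_from_contrast, numeric(1),
                           wide = wide)
  tab$p_gg <- ifelse(
    tab$zero_ss, NA_real_,
    stats::pf(tab$F, tab$gg_epsilon * tab$df_effect,
              tab$gg_epsilon * tab$df_error, lower.tail = FALSE)
  )
  tab
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Within-subject ANOVA of one index (e.g. per-anchor PSE, DL or PMU)
#' against a single 7-level factor, tested against the participant-by-factor
#' interaction; same reporting contract as [rm_anova_twoway()].
#'
#' @inheritParams rm_anova_twoway
#' @param factor_col Name of the within-subject factor column.
#' @return One-row effect tibble (same columns as [rm_anova_twoway()]).
#' @export
rm_anova_oneway <- function(df, value, factor_col = "anchor",
                            participant = "participant_id",
                            on_incomplete = c("error", "drop")) {
  on_incomplete <- match.arg(on_incomplete)
  d <- prepare_rm_data(df, value, factor_col, participant, on_incomplete)
  n <- nlevels(d$.pid)
  if (n < 2) stop("need >= 2 participants for a repeated-measures ANOVA",
                  call. = FALSE)
  fit <- stats::aov(.y ~ .A + Error(.pid / .A), data = d)
  tab <- extract_aov_effects(fit, c(".A" = factor_col))
  wide <- matrix(d$.y[order(d$.pid, d$.A)], nrow = n, byrow = TRUE)
  tab$gg_epsilon <- gg_epsilon_from_contrast(orthonormal_contrasts(nlevels(d$.A)),
                                             wide)
  tab$p_gg <- ifelse(
    tab$zero_ss, NA_real_,
    stats::pf(tab$F, tab$gg_epsilon * tab$df_effect,
              tab$gg_epsilon * tab$df_error, lower.tail = FALSE)
  )
  tab
}

#' Linear anchor contrast of the anchoring effect
#'
#' Scores each participant with the ordered linear contrast
#' `(-3, -2, -1, 0, +1, +2, +3)` over the 7 ascending anchor levels and
#' tests the mean score against zero with a one-sample t-test. With
#' `by = "true_pct"` the contrast is computed separately at each feature
#' percentage, tracing the anchoring-magnitude profile across stimulus
#' levels.
#'
#' @param df Long tibble with one value per participant x anchor (x level
#'   when stratified).
#' @param value Name of the value column.
#' @param by Optional stratification column (e.g. `"true_pct"`).
#' @param participant,anchor Column names.
#' @return Tibble (one row, or one per stratum): `mean_score`, `sd_score`,
#'   `t`, `df`, `p`, `n`, `n_dropped`, plus the per-participant `scores`
#'   as a list column.
#' @export
linear_contrast <- function(df, value, by = NULL,
                            participant = "participant_id", anchor = "anchor") {
  w <- -3:3
  one <- function(d) {
    lv <- sort(unique(d[[anchor]]))
    if (length(lv) != 7) {
      stop("linear contrast requires the 7 ordered anchor levels", call. = FALSE)
    }
    wide <- d |>
      dplyr::select(pid = dplyr::all_of(participant),
                    a = dplyr::all_of(anchor),
                    y = dplyr::all_of(value)) |>
      dplyr::group_by(.data$pid, .data$a) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "a", values_from = "y",
                         names_sort = TRUE)
    complete <- stats::complete.cases(wide)
    n_dropped <- sum(!complete)
    m <- as.matrix(wide[complete, -1])
    scores <- as.vector(m %*% w)
    tt <- if (length(scores) > 1 && stats::sd(scores) > 0) {
      stats::t.test(scores)
    } else NULL
    tibble::tibble(
      mean_score = mean(scores), sd_score = stats::sd(scores),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      n = length(scores), n_dropped = n_dropped,
      scores = list(scores)
    )
  }
  if (is.null(by)) {
    one(df)
  } else {
    res <- df |>
      dplyr::group_by(.data[[by]]) |>
      dplyr::group_modify(function(d, key) one(d)) |>
      dplyr::ungroup()
    res$p_holm <- stats::p.adjust(res$p, method = "holm")
    res
  }
}

#' Format an effect row in the conventional reporting style
#' @param eff One-row effect tibble.
#' @return String like `"F(6, 444) = 109.87, p < .001, eta_p^2 = .60"`.
#' @export
format_effect <- function(eff) {
  pstr <- if (is.na(eff$p)) "p = NA"
  else if (eff$p < 0.001) "p < .001"
  else sprintf("p = %.3f", eff$p)
  sprintf("F(%d, %d) = %.2f, %s, eta_p^2 = %.2f",
          eff$df_effect, eff$df_error, eff$F, pstr, eff$partial_eta_sq)
}

# ---- internals ------------------------------------------------------------

prepare_rm_data <- function(df, value, factors, participant, on_incomplete) {
  cols <- c(participant, factors, value)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- tibble::tibble(
    .pid = factor(df[[participant]]),
    .A = factor(df[[factors[1]]]),
    .y = df[[value]]
  )
  if (length(factors) == 2) d$.B <- factor(df[[factors[2]]])
  n_cells <- nlevels(d$.A) * if (length(factors) == 2) nlevels(d$.B) else 1L
  counts <- table(d$.pid[!is.na(d$.y)])
  incomplete <- names(counts)[counts < n_cells]
  has_na <- unique(d$.pid[is.na(d$.y)])
  incomplete <- union(incomplete, as.character(has_na))
  if (length(incomplete) > 0) {
    if (on_incomplete == "error") {
      stop("participant(s) with missing cells: ",
           paste(utils::head(incomplete, 5), collapse = ", "),
           if (length(incomplete) > 5) ", ..." else "", call. = FALSE)
    }
    d <- d[!(d$.pid %in% incomplete), , drop = FALSE]
    d$.pid <- droplevels(d$.pid)
  }
  if (any(table(d$.pid) != n_cells)) {
    stop("design is unbalanced after filtering", call. = FALSE)
  }
  d
}

extract_aov_effects <- function(fit, effect_names) {
  sm <- summary(fit)
  rows <- lapply(names(effect_names), function(term) {
    stratum <- sm[[paste0("Error: .pid:", term)]]
    if (is.null(stratum)) stop("missing aov stratum for ", term, call. = FALSE)
    s <- stratum[[1]]
    rn <- trimws(rownames(s))
    i_eff <- which(rn == term)
    i_err <- which(rn == "Residuals")
    ss_e <- s$`Sum Sq`[i_eff]; ss_r <- s$`Sum Sq`[i_err]
    df_e <- s$Df[i_eff]; df_r <- s$Df[i_err]
    zero <- isTRUE(ss_e < 1e-12) && isTRUE(ss_r < 1e-12)
    Fv <- if (zero) 0 else (ss_e / df_e) / (ss_r / df_r)
    tibble::tibble(
      effect = effect_names[[term]],
      df_effect = df_e, df_error = df_r,
      ss_effect = ss_e, ss_error = ss_r,
      F = Fv,
      p = if (zero) NA_real_ else stats::pf(Fv, df_e, df_r, lower.tail = FALSE),
      partial_eta_sq = if (ss_e + ss_r < 1e-12) 0 else ss_e / (ss_e + ss_r),
      zero_ss = zero
    )
  })
  dplyr::bind_rows(rows)
}

# k-1 orthonormal rows spanning the deviation-from-mean space of k levels
orthonormal_contrasts <- function(k) {
  c_raw <- stats::contr.helmert(k)
  q <- qr.Q(qr(c_raw))
  t(q)
}

# Greenhouse-Geisser epsilon for the effect picked out by contrast rows C of
# the participant cell-mean vector; S is the between-participant covariance.
gg_epsilon_from_contrast <- function(C, wide) {
  S <- stats::cov(wide)
  M <- C %*% S %*% t(C)
  k <- nrow(M)
  tr <- sum(diag(M))
  denom <- k * sum(M * M)
  if (denom < 1e-300 || tr < 1e-150) return(NA_real_)
  min(tr^2 / denom, 1)
}
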