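#' Anchor and feature-percentage levels of the 7 x 7 design
#'
#' Both the anchor shown in the comparative question and the true feature
#' percentage of the stimulus take the same seven levels, 20% to 80% in
#' 10-point steps.
#'
#' @format Integer vector of length 7.
#' @export
design_levels <- function() seq(20L, 80L, by = 10L)

#' Build one participant's trial design
#'
#' Crosses the 7 anchor levels with the 7 true feature percentages and
#' `n_exemplars` exemplars per cell, assigns each trial a unique stimulus
#' category label (sampled without replacement from a synthetic pool of 14
#' image classes x variants, a simplified stand-in for full counterbalancing),
#' and returns the trials in a seeded random presentation order.
#'
#' @param n_exemplars Number of exemplars per (anchor, true_pct) cell; the
#'   full design uses 7, giving 343 trials.
#' @param seed Integer seed controlling label assignment and trial order.
#' @return A tibble with one row per trial: `set_index`, `anchor`,
#'   `true_pct`, `exemplar_index`, `stimulus_class`, `category_label`.
#' @examples
#' d <- make_design(n_exemplars = 7, seed = 1)
#' nrow(d) # 343
#' @export
make_design <- function(n_exemplars, seed) {
  if (!is.numeric(n_exemplars) || length(n_exemplars) != 1L ||
      is.na(n_exemplars) || n_exemplars < 1) {
    stop("`n_exemplars` must be a single integer >= 1", call. = FALSE)
  }
  n_exemplars <- as.integer(n_exemplars)
  stopifnot(is.numeric(seed), length(seed) == 1L)

  lv <- design_levels()
  grid <- tidyr::expand_grid(
    anchor = lv,
    true_pct = lv,
    exemplar_index = seq_len(n_exemplars)
  )
  n <- nrow(grid)

  # synthetic label pool: 14 image classes, enough variants for uniqueness
  n_classes <- 14L
  n_variants <- ceiling(n / n_classes) + 1L
  pool <- as.vector(outer(
    sprintf("class%02d", seq_len(n_classes)),
    sprintf("v%03d", seq_len(n_variants)),
    paste, sep = "_"
  ))

  withr_seed(seed, {
    labels <- sample(pool, n, replace = FALSE)
    ord <- sample.int(n)
  })

  grid |>
    dplyr::mutate(
      category_label = labels,
      # half the image classes show countable discrete elements, half a
      # continuous extent; the analysis only carries the label
      stimulus_class = ifelse(
        as.integer(sub("class(\\d+)_.*", "\\1", labels)) <= n_classes / 2L,
        "discrete", "continuous"
      )
    ) |>
    dplyr::slice(ord) |>
    dplyr::mutate(set_index = dplyr::row_number(), .before = 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All package randomness goes through this.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic per-participant substream seed, kept inside 32-bit range.
participant_seed <- function(seed, participant_index, stream = 0L) {
  (as.double(seed) * 48271 + participant_index * 10007 + stream * 65537) %%
    2147483629
}
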