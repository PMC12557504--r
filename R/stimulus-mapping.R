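#' Stimulus-mapping configuration
#'
#' Parameters of the reverse-engineering step that asks which stimulus
#' themes coincide with the timepoints MTPA selects most often.
#'
#' @param top_k Number of most frequently selected timepoints forming
#'   the "top" set.
#' @param lag_s Hemodynamic lag (s): neural timepoints are shifted this
#'   many seconds backward to stimulus time before comparison.
#' @param n_shifts Circle-shift permutations.
#' @param zero_cell_correction Additive constant applied to all four
#'   cells of the 2x2 table when any cell is zero (Haldane-Anscombe).
#' @param alternative `"greater"` (one-sided, null odds ratios at or
#'   above the observed) or `"two.sided"`.
#' @param seed Seed for the random shifts.
#' @return A list of class `stimulus_map_config`.
#' @export
stimulus_map_config <- function(top_k = 25, lag_s = 3, n_shifts = 10000,
                                zero_cell_correction = 0.5,
                                alternative = c("greater", "two.sided"),
                                seed = 1L) {
  if (top_k < 1) nl_abort("`top_k` must be at least 1.")
  if (lag_s < 0) nl_abort("`lag_s` must be non-negative.")
  if (n_shifts < 1) nl_abort("`n_shifts` must be at least 1.")
  structure(
    list(top_k = as.integer(top_k), lag_s = lag_s,
         n_shifts = as.integer(n_shifts),
         zero_cell_correction = zero_cell_correction,
         alternative = match.arg(alternative), seed = as.integer(seed)),
    class = "stimulus_map_config"
  )
}

#' Top-selected and never-selected timepoints
#'
#' The top set holds the `top_k` timepoints with the highest selection
#' frequency (ties at the cutoff broken toward the earliest timepoint,
#' deterministically); the never set holds timepoints with selection
#' frequency exactly zero. If fewer than `top_k` timepoints were ever
#' selected, the top set is all of them, with a warning.
#'
#' @param selection_frequency Per-timepoint selection frequencies (the
#'   vector index i corresponds to second i-1).
#' @param cfg A [stimulus_map_config()].
#' @return List with `top` and `never`, both 0-based second indices.
#' @export
top_and_never_selected <- function(selection_frequency,
                                   cfg = stimulus_map_config()) {
  freq <- selection_frequency
  nonzero <- which(freq > 0)
  if (length(nonzero) < cfg$top_k) {
    rlang::warn(sprintf(
      "Only %d timepoints were ever selected (top_k = %d); using all of them.",
      length(nonzero), cfg$top_k))
    top <- nonzero[order(-freq[nonzero], nonzero)]
  } else {
    top <- order(-freq, seq_along(freq))[seq_len(cfg$top_k)]
  }
  list(top = sort(top) - 1L, never = which(freq == 0) - 1L)
}

#' Shift neural timepoints back to stimulus time
#'
#' Accounts for hemodynamic delay: each neural timepoint `t` maps to
#' stimulus second `t - lag_s`; results below zero are dropped.
#'
#' @param timepoints 0-based second indices.
#' @param lag_s Lag in seconds.
#' @return Shifted 0-based indices.
#' @export
apply_lag <- function(timepoints, lag_s) {
  out <- timepoints - lag_s
  out[out >= 0]
}

# Internal: 2x2 counts of theme presence in two disjoint timepoint sets,
# with the zero-cell correction, and the resulting odds ratio.
or_from_sets <- function(top, never, theme_seconds, correction) {
  a <- length(intersect(top, theme_seconds))
  b <- length(top) - a
  c <- length(intersect(never, theme_seconds))
  d <- length(never) - c
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells == 0)) cells <- cells + correction
  list(table = matrix(c(a, b, c, d), 2, 2,
                      dimnames = list(c("theme", "no_theme"),
                                      c("top", "never"))),
       odds_ratio = (cells["a"] * cells["d"]) / (cells["b"] * cells["c"]))
}

#' Odds ratio of theme presence at top vs never-selected timepoints
#'
#' Counts, for a binary per-second theme track, how often the theme is
#' present during the top-selected timepoints versus the never-selected
#' timepoints, and forms the odds ratio with a Haldane-Anscombe
#' correction when any cell is empty.
#'
#' @param top,never Disjoint 0-based second-index sets.
#' @param theme_track Binary per-second vector.
#' @param cfg A [stimulus_map_config()].
#' @return A list of class `odds_ratio_result`: `table` (uncorrected 2x2
#'   counts), `odds_ratio`.
#' @export
theme_odds_ratio <- function(top, never, theme_track,
                             cfg = stimulus_map_config()) {
  if (length(top) == 0 || length(never) == 0) {
    nl_abort("Both the top and never-selected sets must be non-empty.")
  }
  if (length(intersect(top, never)) > 0) {
    nl_abort("Top and never-selected sets must be disjoint.")
  }
  dur <- length(theme_track)
  if (max(c(top, never)) >= dur || min(c(top, never)) < 0) {
    nl_abort("Timepoint outside the theme track.")
  }
  theme_seconds <- which(theme_track == 1) - 1L
  res <- or_from_sets(top, never, theme_seconds, cfg$zero_cell_correction)
  structure(
    list(table = res$table, odds_ratio = unname(res$odds_ratio)),
    class = "odds_ratio_result"
  )
}

#' Circle-shift permutation test for a theme association
#'
#' Breaks the alignment between the top-selected indicator and the theme
#' track while preserving the indicator's autocorrelation structure: the
#' top indicator is circularly rotated by a random integer between 1 s
#' and the track duration minus 1 s, the odds ratio is recomputed
#' against the never-selected set stripped of any overlap with the
#' rotated top set, and the one-sided p-value is the proportion of null
#' odds ratios at or above the observed one.
#'
#' @param top,never Disjoint 0-based second-index sets.
#' @param theme_track Binary per-second vector (length >= 3).
#' @param cfg A [stimulus_map_config()].
#' @return A list of class `odds_ratio_result` with `table`,
#'   `odds_ratio`, `p_value`, `null_odds_ratios`, `n_shifts`.
#' @export
circle_shift_test <- function(top, never, theme_track,
                              cfg = stimulus_map_config()) {
  dur <- length(theme_track)
  if (dur < 3) nl_abort("Theme track must cover at least 3 seconds.")
  obs <- theme_odds_ratio(top, never, theme_track, cfg)
  th <- theme_track == 1
  nev <- logical(dur)
  nev[never + 1L] <- TRUE
  n_never <- length(never)
  corr <- cfg$zero_cell_correction
  shifts <- with_seed(cfg$seed,
                      sample.int(dur - 1L, cfg$n_shifts, replace = TRUE))
  null_or <- vapply(shifts, function(s) {
    idx <- ((top + s) %% dur) + 1L
    a <- sum(th[idx])
    b <- length(idx) - a
    overlap <- nev[idx]
    cc <- sum(th & nev) - sum(th[idx] & overlap)
    dd <- (n_never - sum(overlap)) - cc
    cells <- c(a, b, cc, dd)
    if (any(cells == 0)) cells <- cells + corr
    (cells[1] * cells[4]) / (cells[2] * cells[3])
  }, numeric(1))
  p <- switch(cfg$alternative,
    greater = mean(null_or >= obs$odds_ratio),
    two.sided = mean(pmax(null_or, 1 / null_or) >=
                       max(obs$odds_ratio, 1 / obs$odds_ratio))
  )
  structure(
    list(table = obs$table, odds_ratio = obs$odds_ratio, p_value = p,
         null_odds_ratios = null_or, n_shifts = cfg$n_shifts),
    class = "odds_ratio_result"
  )
}

#' Map selection frequencies onto stimulus themes
#'
#' End-to-end reverse engineering for one fitted MTPA model: derive the
#' top and never-selected sets from the selection-frequency vector,
#' shift both back by the hemodynamic lag, and test each theme with the
#' odds ratio plus circle-shift permutation.
#'
#' @param selection_frequency Per-timepoint selection frequencies (or an
#'   `mtpa_result`).
#' @param theme_tracks Tibble with a `time_s` column and one binary
#'   column per theme.
#' @param cfg A [stimulus_map_config()].
#' @return A tibble: one row per theme with the 2x2 cells, odds ratio
#'   and p-value.
#' @export
map_stimulus_themes <- function(selection_frequency, theme_tracks,
                                cfg = stimulus_map_config()) {
  if (inherits(selection_frequency, "mtpa_result")) {
    selection_frequency <- selection_frequency$selection_frequency
  }
  sets <- top_and_never_selected(selection_frequency, cfg)
  top <- apply_lag(sets$top, cfg$lag_s)
  never <- apply_lag(sets$never, cfg$lag_s)
  themes <- setdiff(names(theme_tracks), "time_s")
  purrr::map_dfr(themes, function(tm) {
    res <- circle_shift_test(top, never, theme_tracks[[tm]], cfg)
    tibble::tibble(
      theme = tm,
      theme_in_top = res$table["theme", "top"],
      no_theme_in_top = res$table["no_theme", "top"],
      theme_in_never = res$table["theme", "never"],
      no_theme_in_never = res$table["no_theme", "never"],
      odds_ratio = res$odds_ratio,
      p_value = res$p_value
    )
  })
}
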