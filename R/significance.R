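#' Maximal-statistic permutation test across ROI-outcome pairs
#'
#' Family-wise inference for the full grid of region-by-outcome
#' classifications: per permutation, outcome labels are shuffled once
#' per measure (the same shuffle is reused across that measure's ROIs,
#' preserving the ROI dependence structure under the null), the full
#' MTPA-LOOCV accuracy is recomputed for every pair, and the maximum
#' accuracy across pairs is recorded. The corrected p-value of a pair is
#' the proportion of null maxima at or above its observed accuracy.
#'
#' @param datasets Named list; each element a list with `roi`, `measure`,
#'   `X` (subjects by timepoints), `y` (binary labels).
#' @param cfg An [mtpa_config()] used for the observed accuracies.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed driving shuffles and permutation-level LOOCV seeds.
#' @param perm_repeats LOOCV repeats inside each permutation (default 1;
#'   the full repeat average inside every permutation is
#'   computationally disproportionate).
#' @param observed Optional named numeric of precomputed observed
#'   accuracies (names matching `datasets`); computed with `cfg` if
#'   missing.
#' @param convention `"count"` (p = count/n) or `"count_plus_one"`
#'   (p = (count+1)/(n+1)).
#' @return A list of class `permutation_result`: `observed` (tibble),
#'   `null_max_accuracies`, `null_matrix` (n_perm by pair), `p_values`
#'   (tibble), `mean_null_max`, `n_perm`, `seed`.
#' @export
max_stat_permutation <- function(datasets, cfg = mtpa_config(),
                                 n_perm = 1000, seed = 1L,
                                 perm_repeats = 1,
                                 observed = NULL,
                                 convention = c("count", "count_plus_one")) {
  convention <- match.arg(convention)
  if (n_perm < 1) nl_abort("`n_perm` must be at least 1.")
  if (length(datasets) < 1) nl_abort("Need at least one (roi, measure) pair.")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- purrr::map_chr(datasets, ~ paste(.x$roi, .x$measure,
                                                        sep = "."))
  }
  measures <- purrr::map_chr(datasets, "measure")
  uniq_meas <- unique(measures)

  if (is.null(observed)) {
    observed <- purrr::map_dbl(datasets, function(d) {
      repeat_loocv(d$X, d$y, cfg, roi = d$roi, measure = d$measure)$accuracy
    })
  }
  stopifnot(setequal(names(observed), names(datasets)))
  observed <- observed[names(datasets)]

  null_mat <- matrix(NA_real_, n_perm, length(datasets),
                     dimnames = list(NULL, names(datasets)))
  for (b in seq_len(n_perm)) {
    # one shuffle seed per measure; pairs of the same measure reuse it
    shuffles <- stats::setNames(
      purrr::map_int(seq_along(uniq_meas),
                     function(m) derive_seed(seed, b * 37L + m)),
      uniq_meas
    )
    cfg_b <- cfg
    cfg_b$n_repeats <- as.integer(perm_repeats)
    cfg_b$seed <- derive_seed(seed, 500000L + b)
    for (j in seq_along(datasets)) {
      d <- datasets[[j]]
      y_perm <- with_seed(shuffles[[d$measure]], sample(as_binary(d$y)))
      null_mat[b, j] <- repeat_loocv(d$X, y_perm, cfg_b)$accuracy
    }
  }
  null_max <- apply(null_mat, 1, max)
  pvals <- vapply(observed, function(a) {
    if (convention == "count") {
      sum(null_max >= a) / n_perm
    } else {
      (sum(null_max >= a) + 1) / (n_perm + 1)
    }
  }, numeric(1))
  structure(
    list(
      observed = tibble::tibble(
        pair = names(datasets),
        roi = purrr::map_chr(datasets, "roi"),
        measure = measures,
        accuracy = unname(observed)
      ),
      null_max_accuracies = null_max,
      null_matrix = null_mat,
      p_values = tibble::tibble(pair = names(datasets),
                                p_value = unname(pvals)),
      mean_null_max = mean(null_max),
      n_perm = n_perm, seed = seed, convention = convention
    ),
    class = "permutation_result"
  )
}

#' Summary of the null distribution of maximal accuracies
#'
#' @param result A [max_stat_permutation()] result.
#' @return A tibble with the mean and the 50/95/99% quantiles of the
#'   null maxima.
#' @export
summarize_null <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  q <- stats::quantile(result$null_max_accuracies, c(0.5, 0.95, 0.99),
                       names = FALSE)
  tibble::tibble(mean_null_max = mean(result$null_max_accuracies),
                 q50 = q[1], q95 = q[2], q99 = q[3])
}

#' @export
tidy.permutation_result <- function(x, ...) {
  dplyr::left_join(x$observed, x$p_values, by = "pair")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Maximal-statistic permutation test: %d pairs, %d permutations\n",
    nrow(x$observed), x$n_perm))
  cat(sprintf("Mean null max accuracy: %.2f%%\n", 100 * x$mean_null_max))
  print(tidy(x))
  invisible(x)
}
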