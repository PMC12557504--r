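#' Most balanced binary split of Likert responses
#'
#' Dichotomizes 1-7 responses into high/low reference groups by the
#' threshold that makes the two classes as even as possible. Candidate
#' thresholds are enumerated exhaustively: half-integers (1.5, ..., 6.5),
#' which omit nobody, and integers (2, ..., 6), which omit respondents
#' sitting exactly on the threshold. The split minimizing
#' `|n_high - n_low|` wins; ties are broken toward half-integer
#' thresholds (no omission), then fewer omissions, then toward the scale
#' centre, then toward the lower threshold.
#'
#' @param responses Integer vector of 1-7 responses.
#' @param ids Optional participant identifiers (defaults to positions).
#' @param measure Optional measure name carried into the result.
#' @return A list of class `outcome_labels`: `measure`, `threshold`,
#'   `labels` (tibble `participant_id`, `response`, `label`), `omitted`
#'   (ids), `class_counts` (named `n_high`, `n_low`).
#' @export
most_balanced_split <- function(responses, ids = NULL, measure = NA_character_) {
  if (any(!responses %in% 1:7)) {
    nl_abort("Responses must be integers on the 1-7 scale.")
  }
  if (length(unique(responses)) < 2) {
    nl_abort("All responses identical: no valid split exists.")
  }
  if (is.null(ids)) ids <- as.character(seq_along(responses))
  cand <- tibble::tibble(
    threshold = c(seq(1.5, 6.5, by = 1), 2:6),
    integer_split = c(rep(FALSE, 6), rep(TRUE, 5))
  )
  eval_one <- function(thr, int) {
    omitted <- if (int) responses == thr else rep(FALSE, length(responses))
    n_high <- sum(responses > thr)
    n_low <- sum(responses[!omitted] < thr)
    c(imbalance = abs(n_high - n_low), n_omitted = sum(omitted),
      n_high = n_high, n_low = n_low)
  }
  scores <- purrr::map2(cand$threshold, cand$integer_split, eval_one)
  cand <- dplyr::bind_cols(cand, dplyr::bind_rows(purrr::map(scores, as.list)))
  cand <- cand |>
    dplyr::arrange(.data$imbalance, .data$integer_split, .data$n_omitted,
                   abs(.data$threshold - 4), .data$threshold)
  best <- cand[1, ]
  thr <- best$threshold
  omit <- best$integer_split & responses == thr
  labels <- tibble::tibble(
    participant_id = ids[!omit],
    response = responses[!omit],
    label = ifelse(responses[!omit] > thr, "high", "low")
  )
  structure(
    list(measure = measure, threshold = thr, labels = labels,
         omitted = ids[omit],
         class_counts = c(n_high = best$n_high, n_low = best$n_low)),
    class = "outcome_labels"
  )
}

#' Decide whether a dichotomized measure is analyzable
#'
#' Formalizes the narrative criteria for excluding a measure whose best
#' split is degenerate: a threshold at the scale extremes, classes more
#' imbalanced than `min_class_fraction`, or too many respondents omitted
#' at an integer threshold.
#'
#' @param labels An [most_balanced_split()] result.
#' @param min_class_fraction Minimum admissible minority-class share.
#' @param max_omitted_fraction Maximum admissible omitted share.
#' @param extreme_thresholds Thresholds at or beyond these bounds are
#'   deemed uninterpretable.
#' @return List with `keep` (logical) and `reasons` (character).
#' @export
drop_degenerate_measure <- function(labels,
                                    min_class_fraction = 0.35,
                                    max_omitted_fraction = 0.15,
                                    extreme_thresholds = c(2, 6)) {
  stopifnot(inherits(labels, "outcome_labels"))
  n <- sum(labels$class_counts)
  n_total <- n + length(labels$omitted)
  reasons <- character(0)
  if (labels$threshold <= extreme_thresholds[1] ||
      labels$threshold >= extreme_thresholds[2]) {
    reasons <- c(reasons, sprintf("split at scale extreme (threshold %g)",
                                  labels$threshold))
  }
  if (min(labels$class_counts) / n < min_class_fraction) {
    reasons <- c(reasons, sprintf("imbalanced classes (%d/%d)",
                                  labels$class_counts[["n_high"]],
                                  labels$class_counts[["n_low"]]))
  }
  if (length(labels$omitted) / n_total > max_omitted_fraction) {
    reasons <- c(reasons, sprintf("%d of %d respondents omitted at threshold",
                                  length(labels$omitted), n_total))
  }
  list(keep = length(reasons) == 0, reasons = reasons)
}

#' Upsample the minority class by randomized repetition
#'
#' Balances a training fold by repeating randomly chosen minority-class
#' cases (with replacement) until the classes are equal; the majority
#' class is untouched and every original case is kept. Called inside
#' every cross-validation fold so the repeated cases change from fold to
#' fold and repeat to repeat; the function sees training labels only, so
#' the held-out case can never be replicated into training.
#'
#' @param train_labels Binary (0/1 or two-level) training labels.
#' @param seed Seed for the randomized repetition.
#' @return Integer indices into the training sample of class
#'   `balanced_index` (attribute `seed` records the seed).
#' @export
upsample_minority <- function(train_labels, seed = 1L) {
  y <- as.integer(factor(train_labels)) - 1L
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n0 == 0 || n1 == 0) nl_abort("Both classes must be non-empty.")
  idx <- seq_along(y)
  if (n0 != n1) {
    minority <- if (n0 < n1) which(y == 0L) else which(y == 1L)
    extra <- with_seed(seed,
      minority[sample.int(length(minority), abs(n1 - n0), replace = TRUE)])
    idx <- c(idx, extra)
  }
  structure(idx, class = "balanced_index", seed = seed)
}
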