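#' Run the full lens-decoding study
#'
#' Orchestrates every stage on a cohort: preprocessing, balanced
#' dichotomization of each outcome measure (degenerate measures are
#' dropped with a logged reason), repeated-LOOCV MTPA for every
#' ROI-by-measure pair, family-wise maximal-statistic permutation
#' inference, and stimulus-theme mapping for the pairs surviving
#' correction. A single `seed` drives all stochastic steps; reruns with
#' the same inputs are identical.
#'
#' @param cohort A [generate_cohort()] / [read_cohort()] cohort.
#' @param preprocess_cfg A [preprocess_config()].
#' @param mtpa_cfg An [mtpa_config()] (its `seed` is overridden by a
#'   seed derived from `seed`).
#' @param stim_cfg A [stimulus_map_config()] (likewise).
#' @param n_perm Permutations for the maximal-statistic test.
#' @param perm_repeats LOOCV repeats inside each permutation.
#' @param alpha Family-wise significance level.
#' @param seed Master seed.
#' @param output_dir Optional directory for result files (Table-1-style
#'   CSV, permutation JSON + null CSV, per-theme CSV).
#' @return A list of class `lens_study`.
#' @export
run_full_study <- function(cohort,
                           preprocess_cfg = preprocess_config(),
                           mtpa_cfg = mtpa_config(),
                           stim_cfg = stimulus_map_config(),
                           n_perm = 1000,
                           perm_repeats = 1,
                           alpha = 0.05,
                           seed = 1L,
                           output_dir = NULL) {
  mtpa_cfg$seed <- derive_seed(seed, 1L)
  stim_cfg$seed <- derive_seed(seed, 2L)

  processed <- preprocess_cohort(cohort, preprocess_cfg)
  rois <- unique(processed$series$roi)

  measures <- unique(cohort$likert$measure)
  label_sets <- list()
  dropped <- list()
  for (m in measures) {
    resp <- dplyr::filter(cohort$likert, .data$measure == m)
    lab <- most_balanced_split(resp$response, ids = resp$participant_id,
                               measure = m)
    verdict <- drop_degenerate_measure(lab)
    if (verdict$keep) {
      label_sets[[m]] <- lab
    } else {
      dropped[[m]] <- verdict$reasons
    }
  }
  if (length(label_sets) == 0) nl_abort("No analyzable outcome measure.")

  datasets <- list()
  fits <- list()
  for (r in rois) {
    Xr <- feature_matrix(processed, r)
    for (m in names(label_sets)) {
      lab <- label_sets[[m]]
      ids <- intersect(rownames(Xr), lab$labels$participant_id)
      y <- lab$labels$label[match(ids, lab$labels$participant_id)]
      y <- as.integer(y == "high")
      if (length(ids) < 4 || min(table(y)) < 2) next
      key <- paste(r, m, sep = ".")
      datasets[[key]] <- list(roi = r, measure = m,
                              X = Xr[ids, , drop = FALSE], y = y)
    }
  }
  if (length(datasets) == 0) nl_abort("No (ROI, measure) pair is analyzable.")

  fits <- purrr::map(datasets, function(d) {
    repeat_loocv(d$X, d$y, mtpa_cfg, roi = d$roi, measure = d$measure)
  })
  observed <- purrr::map_dbl(fits, "accuracy")

  perm <- max_stat_permutation(datasets, mtpa_cfg, n_perm = n_perm,
                               seed = derive_seed(seed, 3L),
                               perm_repeats = perm_repeats,
                               observed = observed)
  results <- tidy(perm) |>
    dplyr::mutate(
      accuracy_pct = 100 * .data$accuracy,
      mean_n_features = purrr::map_dbl(fits[.data$pair], "mean_n_features"),
      significant = .data$p_value <= alpha
    ) |>
    dplyr::arrange(.data$measure, .data$roi)

  stimulus <- list()
  sig_pairs <- results$pair[results$significant]
  for (key in sig_pairs) {
    stimulus[[key]] <- map_stimulus_themes(fits[[key]],
                                           cohort$theme_tracks, stim_cfg)
  }

  study <- structure(
    list(results = results, fits = fits, permutation = perm,
         stimulus = stimulus, labels = label_sets,
         dropped_measures = dropped,
         qc = list(qc_log = processed$qc_log, missing = processed$missing,
                   retained = processed$retained),
         config = list(preprocess = preprocess_cfg, mtpa = mtpa_cfg,
                       stimulus = stim_cfg, n_perm = n_perm,
                       perm_repeats = perm_repeats, alpha = alpha,
                       seed = seed)),
    class = "lens_study"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(
      dplyr::select(results, "measure", "roi", "accuracy_pct",
                    "mean_n_features", "p_value", "significant"),
      file.path(output_dir, "results_table.csv"))
    write_permutation_result(perm,
                             file.path(output_dir, "permutation.json"),
                             file.path(output_dir, "null_max.csv"))
    for (key in names(stimulus)) {
      readr::write_csv(stimulus[[key]],
                       file.path(output_dir,
                                 paste0("themes_", key, ".csv")))
    }
  }
  study
}

#' @export
print.lens_study <- function(x, ...) {
  cat("Lens-decoding study\n")
  cat(sprintf("  %d ROI x measure pairs, %d permutations\n",
              nrow(x$results), x$permutation$n_perm))
  if (length(x$dropped_measures) > 0) {
    cat(sprintf("  dropped measures: %s\n",
                paste(names(x$dropped_measures), collapse = ", ")))
  }
  print(dplyr::select(x$results, "measure", "roi", "accuracy_pct",
                      "mean_n_features", "p_value", "significant"))
  invisible(x)
}

#' @export
tidy.lens_study <- function(x, ...) {
  x$results
}

#' @export
glance.lens_study <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_perm = x$permutation$n_perm,
    mean_null_max = x$permutation$mean_null_max,
    n_dropped_measures = length(x$dropped_measures)
  )
}
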