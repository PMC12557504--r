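#' Plot per-timepoint selection frequencies
#'
#' Vertical bars mark the timepoints the elastic net retained, darker
#' bars for timepoints selected in a larger share of folds and repeats;
#' optional group-mean ROI timeseries are overlaid for visual
#' inspection of where the groups diverge.
#'
#' @param result An [repeat_loocv()] result.
#' @param group_means Optional tibble with columns `time_s`, `value`,
#'   `group` (e.g. the two class-mean timeseries).
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(result, group_means = NULL) {
  df <- tidy(result)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_col(
      data = dplyr::filter(df, .data$selection_frequency > 0),
      ggplot2::aes(y = max(df$selection_frequency),
                   alpha = .data$selection_frequency),
      width = 1, fill = "grey20"
    ) +
    ggplot2::scale_alpha(range = c(0.15, 1), name = "selection\nfrequency") +
    ggplot2::labs(
      x = "stimulus time (s)", y = NULL,
      title = sprintf("%s / %s: %.1f%% accuracy, %.1f features",
                      result$roi, result$measure, 100 * result$accuracy,
                      result$mean_n_features)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(group_means)) {
    p <- p + ggplot2::geom_line(
      data = group_means,
      ggplot2::aes(y = .data$value, colour = factor(.data$group))
    ) +
      ggplot2::scale_colour_manual(values = c("steelblue", "firebrick"),
                                   name = "group")
  }
  p
}

#' Histogram of the null maximal accuracies
#'
#' The null distribution from the maximal-statistic permutation test,
#' with vertical lines at the observed accuracies of each pair.
#'
#' @param object A [max_stat_permutation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  nulls <- tibble::tibble(accuracy = object$null_max_accuracies)
  ggplot2::ggplot(nulls, ggplot2::aes(x = 100 * .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = object$observed,
      ggplot2::aes(xintercept = 100 * .data$accuracy),
      colour = "darkorange", linewidth = 0.8
    ) +
    ggplot2::labs(x = "maximal null accuracy (%)", y = "permutations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Barplot of theme probabilities at top vs never-selected timepoints
#'
#' @param theme_map A [map_stimulus_themes()] tibble.
#' @return A ggplot object.
#' @export
plot_theme_association <- function(theme_map) {
  df <- theme_map |>
    dplyr::mutate(
      top = .data$theme_in_top /
        (.data$theme_in_top + .data$no_theme_in_top),
      never = .data$theme_in_never /
        (.data$theme_in_never + .data$no_theme_in_never)
    ) |>
    tidyr::pivot_longer(c("top", "never"), names_to = "set",
                        values_to = "probability")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theme, y = .data$probability,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(top = "darkorange",
                                          never = "grey60")) +
    ggplot2::labs(x = NULL, y = "P(theme | timepoint set)") +
    ggplot2::theme_minimal()
}
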