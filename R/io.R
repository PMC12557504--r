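# Internal: read a CSV and fail with a located, human-readable error
read_csv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) nl_abort(sprintf("File not found: %s", path))
  out <- tryCatch(
    suppressWarnings(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ),
    error = function(e) nl_abort(sprintf("Failed to parse %s: %s", path,
                                         conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    nl_abort(sprintf("Parse error in %s at line %d: expected %s, got %s",
                     path, probs$row[1] + 1L, probs$expected[1],
                     probs$actual[1]))
  }
  missing <- setdiff(required_cols, names(out))
  if (length(missing) > 0) {
    nl_abort(sprintf("%s is missing required column(s): %s", path,
                     paste(missing, collapse = ", ")))
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' One CSV per participant (`time_s` plus one optical-density column per
#' channel-wavelength) and a JSON sidecar with the sampling rate, the
#' channel-to-ROI map, true group labels and planted timepoints, plus
#' CSVs for the theme tracks and Likert responses.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    df <- tibble::as_tibble(rec$od)
    df <- dplyr::mutate(df,
                        time_s = (seq_len(nrow(rec$od)) - 1) / rec$fs_hz,
                        .before = 1)
    readr::write_csv(df, file.path(dir, paste0(rec$participant_id, ".csv")))
  }
  rec1 <- cohort$recordings[[1]]
  sidecar <- list(
    fs_hz = rec1$fs_hz,
    wavelengths = rec1$wavelengths,
    channel_roi_map = rec1$channel_roi_map,
    participants = purrr::map_chr(cohort$recordings, "participant_id"),
    true_group = cohort$true_group,
    planted_timepoints = cohort$planted_timepoints
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(cohort$theme_tracks, file.path(dir, "theme_tracks.csv"))
  readr::write_csv(cohort$likert, file.path(dir, "likert.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list of class `synthetic_cohort` (without the latent
#'   diagnostic series).
#' @export
read_cohort <- function(dir) {
  side_path <- file.path(dir, "cohort.json")
  if (!file.exists(side_path)) {
    nl_abort(sprintf("Missing cohort sidecar: %s", side_path))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  chmap <- tibble::as_tibble(side$channel_roi_map)
  recordings <- purrr::map(side$participants, function(pid) {
    df <- read_csv_checked(file.path(dir, paste0(pid, ".csv")),
                           required_cols = "time_s")
    od <- as.matrix(df[, setdiff(names(df), "time_s")])
    raw_recording(pid, side$fs_hz, od, chmap,
                  wavelengths = side$wavelengths)
  })
  structure(
    list(recordings = recordings,
         true_group = as.integer(side$true_group),
         planted_timepoints = as.integer(side$planted_timepoints),
         theme_tracks = read_csv_checked(file.path(dir, "theme_tracks.csv"),
                                         required_cols = "time_s"),
         likert = read_csv_checked(
           file.path(dir, "likert.csv"),
           required_cols = c("participant_id", "measure", "response")),
         latent_roi = NULL, spec = NULL),
    class = "synthetic_cohort"
  )
}

#' Write preprocessed ROI timeseries
#'
#' Long CSV (`participant_id`, `roi`, `time_s`, `value`) plus a JSON
#' quality-control log.
#'
#' @param processed A [preprocess_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_roi_timeseries <- function(processed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(processed$series, file.path(dir, "roi_timeseries.csv"))
  jsonlite::write_json(
    list(qc_log = processed$qc_log, retained = processed$retained,
         missing = processed$missing),
    file.path(dir, "qc_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read preprocessed ROI timeseries written by [write_roi_timeseries()]
#'
#' @param dir Directory.
#' @return A `preprocessed_cohort`-shaped list.
#' @export
read_roi_timeseries <- function(dir) {
  series <- read_csv_checked(
    file.path(dir, "roi_timeseries.csv"),
    required_cols = c("participant_id", "roi", "time_s", "value"))
  qc <- jsonlite::read_json(file.path(dir, "qc_log.json"),
                            simplifyVector = TRUE)
  structure(list(series = series,
                 qc_log = tibble::as_tibble(qc$qc_log),
                 retained = tibble::as_tibble(qc$retained),
                 missing = tibble::as_tibble(qc$missing)),
            class = "preprocessed_cohort")
}

#' Write outcome labels to JSON
#'
#' @param labels An [most_balanced_split()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  jsonlite::write_json(
    list(measure = labels$measure, threshold = labels$threshold,
         labels = labels$labels, omitted = labels$omitted,
         class_counts = as.list(labels$class_counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read outcome labels written by [write_labels()]
#'
#' @param path JSON path.
#' @return An `outcome_labels` object.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) nl_abort(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(measure = x$measure, threshold = x$threshold,
         labels = tibble::as_tibble(x$labels),
         omitted = as.character(x$omitted),
         class_counts = unlist(x$class_counts)),
    class = "outcome_labels"
  )
}

#' Write a feature matrix (participants by timepoints) to CSV
#'
#' @param m Matrix with participant ids as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- paste0("t", seq_len(ncol(m)) - 1)
  df <- dplyr::mutate(df, participant_id = rownames(m), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return Matrix with participant ids as row names.
#' @export
read_feature_matrix <- function(path) {
  df <- read_csv_checked(path, required_cols = "participant_id")
  m <- as.matrix(df[, setdiff(names(df), "participant_id")])
  rownames(m) <- df$participant_id
  m
}

#' Write an MTPA result to JSON (and optionally a selection CSV)
#'
#' @param result An [repeat_loocv()] result.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV of per-timepoint selection frequencies.
#' @return `json_path`, invisibly.
#' @export
write_mtpa_result <- function(result, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(roi = result$roi, measure = result$measure,
         accuracy = result$accuracy,
         per_repeat_accuracies = result$per_repeat_accuracies,
         selection_frequency = result$selection_frequency,
         mean_n_features = result$mean_n_features,
         n_participants = result$n_participants,
         n_timepoints = result$n_timepoints,
         n_repeats = result$n_repeats),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) readr::write_csv(tidy(result), csv_path)
  invisible(json_path)
}

#' Write a permutation result to JSON (and optionally the null vector)
#'
#' @param result A [max_stat_permutation()] result.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV of the null maximal accuracies.
#' @return `json_path`, invisibly.
#' @export
write_permutation_result <- function(result, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(observed = result$observed, p_values = result$p_values,
         mean_null_max = result$mean_null_max, n_perm = result$n_perm,
         seed = result$seed, convention = result$convention),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    readr::write_csv(
      tibble::tibble(null_max_accuracy = result$null_max_accuracies),
      csv_path)
  }
  invisible(json_path)
}
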