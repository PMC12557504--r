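#' Tabulated molar extinction coefficients for hemoglobin
#'
#' Standard compiled extinction coefficients for oxygenated (HbO) and
#' deoxygenated (HbR) hemoglobin at the two acquisition wavelengths,
#' in cm^-1 / (mol/L). Used by the modified Beer-Lambert inversion.
#'
#' @return A tibble with columns `wavelength_nm`, `hbo`, `hbr`.
#' @export
extinction_coefficients <- function() {
  tibble::tibble(
    wavelength_nm = c(760, 850),
    hbo = c(1486.5865, 2526.391),
    hbr = c(3843.707, 1798.643)
  )
}

#' Preprocessing configuration
#'
#' Parameters of the fNIRS cleaning chain. Defaults follow standard
#' continuous-wave fNIRS practice: channel rejection by a sliding quartile
#' coefficient of dispersion (QCD) against the sampling-rate-dependent
#' cutoff `cthresh_intercept - cthresh_slope * fs`, removal of motion
#' spikes exceeding `spike_sd_threshold` standard deviations within less
#' than `spike_max_window_s` seconds, a conservative zero-phase bandpass
#' (0.008-0.2 Hz) that excises baseline drift plus cardiac (~1 Hz) and
#' respiratory (~0.3 Hz) oscillations, and the modified Beer-Lambert
#' inversion with a 3-cm source-detector separation and a differential
#' pathlength factor of 6 at both wavelengths.
#'
#' @param cthresh_intercept,cthresh_slope Coefficients of the QCD cutoff.
#' @param cthresh_min_duration_s Seconds the QCD must stay above the
#'   cutoff for a channel to be rejected.
#' @param qcd_window_s Length (s) of the centred sliding window on which
#'   the QCD is computed. The default is twice
#'   `cthresh_min_duration_s`: quartiles react once a disturbance
#'   occupies at least half a window, so dispersion bursts shorter than
#'   the persistence criterion cannot trip the rejection rule.
#' @param spike_sd_threshold Motion-spike threshold in global SD units.
#' @param spike_max_window_s Spikes are changes faster than this (s).
#' @param bandpass_low_hz,bandpass_high_hz Passband edges (Hz).
#' @param filter_order Butterworth prototype order (applied
#'   forward-backward, doubling the effective order).
#' @param dpf Named numeric: differential pathlength factor per wavelength.
#' @param source_detector_distance_cm Optode separation (cm).
#' @param extinction Extinction coefficient table; see
#'   [extinction_coefficients()].
#' @param autocorr_delta_threshold Maximum admissible change in lag-1
#'   autocorrelation induced by motion correction.
#' @param target_fs_hz Output sampling rate after resampling (Hz).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cthresh_intercept = 0.6,
                              cthresh_slope = 0.03,
                              cthresh_min_duration_s = 2,
                              qcd_window_s = 4,
                              spike_sd_threshold = 5,
                              spike_max_window_s = 1,
                              bandpass_low_hz = 0.008,
                              bandpass_high_hz = 0.2,
                              filter_order = 2,
                              dpf = c("760" = 6, "850" = 6),
                              source_detector_distance_cm = 3,
                              extinction = extinction_coefficients(),
                              autocorr_delta_threshold = 0.1,
                              target_fs_hz = 1) {
  check_positive(bandpass_low_hz, "bandpass_low_hz")
  check_positive(bandpass_high_hz, "bandpass_high_hz")
  if (bandpass_low_hz >= bandpass_high_hz) {
    nl_abort("`bandpass_low_hz` must be below `bandpass_high_hz`.")
  }
  check_positive(spike_sd_threshold, "spike_sd_threshold")
  check_positive(qcd_window_s, "qcd_window_s")
  check_positive(target_fs_hz, "target_fs_hz")
  structure(
    list(
      cthresh_intercept = cthresh_intercept,
      cthresh_slope = cthresh_slope,
      cthresh_min_duration_s = cthresh_min_duration_s,
      qcd_window_s = qcd_window_s,
      spike_sd_threshold = spike_sd_threshold,
      spike_max_window_s = spike_max_window_s,
      bandpass_low_hz = bandpass_low_hz,
      bandpass_high_hz = bandpass_high_hz,
      filter_order = filter_order,
      dpf = dpf,
      source_detector_distance_cm = source_detector_distance_cm,
      extinction = extinction,
      autocorr_delta_threshold = autocorr_delta_threshold,
      target_fs_hz = target_fs_hz
    ),
    class = "preprocess_config"
  )
}

#' Raw dual-wavelength recording
#'
#' Container for one participant's stimulus-locked optical-density
#' timeseries. Columns of `od` are named `"<channel>@<wavelength>"`,
#' e.g. `"TPJ_1@760"`.
#'
#' @param participant_id Identifier.
#' @param fs_hz Sampling rate (Hz).
#' @param od Numeric matrix, time by (channel x wavelength).
#' @param channel_roi_map Tibble with columns `channel`, `roi`.
#' @param wavelengths Acquisition wavelengths (nm).
#' @return A list of class `raw_recording`.
#' @export
raw_recording <- function(participant_id, fs_hz, od, channel_roi_map,
                          wavelengths = c(760, 850)) {
  check_positive(fs_hz, "fs_hz")
  stopifnot(is.matrix(od), nrow(od) > 0)
  expected <- as.vector(outer(channel_roi_map$channel, wavelengths,
                              function(ch, wl) paste0(ch, "@", wl)))
  if (!setequal(colnames(od), expected)) {
    nl_abort("`od` column names do not match channel_roi_map x wavelengths.")
  }
  structure(
    list(
      participant_id = participant_id,
      fs_hz = fs_hz,
      od = od[, sort(colnames(od)), drop = FALSE],
      channel_roi_map = channel_roi_map,
      wavelengths = wavelengths
    ),
    class = "raw_recording"
  )
}

#' QCD channel-rejection cutoff
#'
#' The dispersion cutoff scales down with sampling rate:
#' `Cthresh = intercept - slope * fs`, floored at zero.
#'
#' @param fs_hz Sampling rate (Hz); must be non-negative.
#' @param intercept,slope Cutoff coefficients.
#' @return The cutoff value.
#' @export
#' @examples
#' compute_cthresh(3.906) # 0.48282
compute_cthresh <- function(fs_hz, intercept = 0.6, slope = 0.03) {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || is.na(fs_hz) || fs_hz < 0) {
    nl_abort("`fs_hz` must be a single non-negative number.")
  }
  max(0, intercept - slope * fs_hz)
}

#' Sliding (modified) quartile coefficient of dispersion
#'
#' Time-resolved robust dispersion: for each sample, the quartiles of a
#' centred window (truncated at the series edges) give
#' `QCD = (Q3 - Q1) / |Q3 + Q1|`. The absolute denominator keeps the
#' index positive for signals fluctuating around zero; a window with
#' `Q3 + Q1 == 0` yields 0 when the IQR is also zero and Inf otherwise.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate (Hz).
#' @param window_s Window length in seconds.
#' @return Numeric vector of per-sample QCD values.
#' @export
sliding_qcd <- function(x, fs_hz, window_s = 1) {
  n <- length(x)
  half <- max(1L, floor(window_s * fs_hz / 2))
  qcd_of <- function(q1, q3) {
    s <- abs(q3 + q1)
    ifelse(s == 0, ifelse(q3 - q1 == 0, 0, Inf), (q3 - q1) / s)
  }
  if (half == 1L && n >= 3L) {
    # vectorized 3-sample windows (type-7 quartiles of a sorted triple)
    a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; c <- x[3:n]
    lo <- pmin(a, b, c); hi <- pmax(a, b, c)
    mid <- a + b + c - lo - hi
    out <- numeric(n)
    out[2:(n - 1)] <- qcd_of(lo + 0.5 * (mid - lo), mid + 0.5 * (hi - mid))
    for (i in c(1L, n)) {
      w <- sort(x[max(1L, i - 1L):min(n, i + 1L)][1:2])
      out[i] <- qcd_of(w[1] + 0.25 * (w[2] - w[1]),
                       w[1] + 0.75 * (w[2] - w[1]))
    }
    return(out)
  }
  w <- 2L * half + 1L
  h1 <- (w - 1) * 0.25 + 1
  h3 <- (w - 1) * 0.75 + 1
  f1 <- floor(h1); f3 <- floor(h3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half
    if (lo >= 1L && hi <= n) {
      s <- sort.int(x[lo:hi], method = "quick")
      q1 <- s[f1] + (h1 - f1) * (s[f1 + 1L] - s[f1])
      q3 <- s[f3] + (h3 - f3) * (s[min(f3 + 1L, w)] - s[f3])
    } else {
      s <- sort.int(x[max(1L, lo):min(n, hi)], method = "quick")
      m <- length(s)
      g1 <- (m - 1) * 0.25 + 1
      g3 <- (m - 1) * 0.75 + 1
      q1 <- s[floor(g1)] +
        (g1 - floor(g1)) * (s[min(floor(g1) + 1L, m)] - s[floor(g1)])
      q3 <- s[floor(g3)] +
        (g3 - floor(g3)) * (s[min(floor(g3) + 1L, m)] - s[floor(g3)])
    }
    out[i] <- qcd_of(q1, q3)
  }
  out
}

# Internal: TRUE iff `flag` contains a run of at least `min_run` TRUEs
has_run <- function(flag, min_run) {
  r <- rle(flag)
  any(r$values & r$lengths >= min_run)
}

#' Reject noisy or saturated channels by sliding QCD
#'
#' A channel is removed when its windowed QCD exceeds the cutoff
#' continuously for at least `cthresh_min_duration_s` seconds on either
#' wavelength.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [preprocess_config()].
#' @return List with `mask` (named logical per channel, TRUE = retained)
#'   and `qc_log` (tibble of rejections).
#' @export
reject_channels_qcd <- function(rec, cfg = preprocess_config()) {
  fs <- rec$fs_hz
  n <- nrow(rec$od)
  if (n / fs < cfg$cthresh_min_duration_s) {
    nl_abort("Recording shorter than the QCD persistence window.")
  }
  cthresh <- compute_cthresh(fs, cfg$cthresh_intercept, cfg$cthresh_slope)
  min_run <- ceiling(cfg$cthresh_min_duration_s * fs)
  channels <- rec$channel_roi_map$channel
  mask <- stats::setNames(rep(TRUE, length(channels)), channels)
  log <- list()
  for (ch in channels) {
    for (wl in rec$wavelengths) {
      q <- sliding_qcd(rec$od[, paste0(ch, "@", wl)], fs, cfg$qcd_window_s)
      if (has_run(q > cthresh, min_run)) {
        mask[ch] <- FALSE
        log[[length(log) + 1L]] <- tibble::tibble(
          channel = ch, stage = "qcd",
          reason = sprintf("QCD > %.4f for >= %gs at %dnm",
                           cthresh, cfg$cthresh_min_duration_s, wl)
        )
        break
      }
    }
  }
  list(mask = mask, qc_log = dplyr::bind_rows(log))
}

#' Remove motion spikes
#'
#' A sample is flagged as a motion spike when it differs by more than
#' `spike_sd_threshold` global standard deviations from some sample less
#' than `spike_max_window_s` seconds away on each side (the transient
#' departs and returns; series edges use the available side only).
#' Flagged samples are replaced by linear interpolation between
#' non-flagged neighbours, preserving series length.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate (Hz).
#' @param cfg A [preprocess_config()].
#' @return List with `series` (cleaned) and `spike_idx` (flagged indices).
#' @export
remove_motion_spikes <- function(x, fs_hz, cfg = preprocess_config()) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(list(series = x, spike_idx = integer(0)))
  }
  thr <- cfg$spike_sd_threshold * s
  max_lag <- max(1L, ceiling(fs_hz * cfg$spike_max_window_s) - 1L)
  left <- right <- rep(FALSE, n)
  for (lag in seq_len(max_lag)) {
    d <- abs(diff(x, lag = lag)) > thr
    right[seq_len(n - lag)] <- right[seq_len(n - lag)] | d
    left[(lag + 1L):n] <- left[(lag + 1L):n] | d
  }
  flag <- (left & right)
  flag[seq_len(min(max_lag, n))] <- flag[seq_len(min(max_lag, n))] |
    (right & !left)[seq_len(min(max_lag, n))]
  tail_idx <- seq.int(max(1L, n - max_lag + 1L), n)
  flag[tail_idx] <- flag[tail_idx] | (left & !right)[tail_idx]
  idx <- which(flag)
  if (length(idx) > 0 && length(idx) < n) {
    keep <- setdiff(seq_len(n), idx)
    x[idx] <- stats::approx(keep, x[keep], xout = idx, rule = 2)$y
  }
  list(series = x, spike_idx = idx)
}

#' Zero-phase Butterworth bandpass
#'
#' Band-limits the series to `[bandpass_low_hz, bandpass_high_hz]` with a
#' Butterworth filter applied forward and backward (zero phase). The
#' series is extended by even mirror reflection before filtering to
#' suppress edge transients from the very low high-pass corner.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate (Hz); the high cutoff must lie below the
#'   Nyquist frequency.
#' @param cfg A [preprocess_config()].
#' @return Filtered series of the same length.
#' @export
bandpass_filter <- function(x, fs_hz, cfg = preprocess_config()) {
  if (cfg$bandpass_high_hz >= fs_hz / 2) {
    nl_abort("High cutoff must be below the Nyquist frequency.")
  }
  n <- length(x)
  if (n <= 6 * (2 * cfg$filter_order + 1)) {
    nl_abort("Series too short for the bandpass filter warm-up.")
  }
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$bandpass_low_hz, cfg$bandpass_high_hz) / (fs_hz / 2),
                       type = "pass")
  np <- min(n - 1L, ceiling(2.5 * fs_hz / cfg$bandpass_low_hz))
  pre <- x[(np + 1L):2L]
  post <- x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1L):(np + n)]
}

#' Modified Beer-Lambert inversion
#'
#' Solves, per timepoint, the two-wavelength system
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR) * d * DPF(lambda)`
#' for the oxygenated and deoxygenated hemoglobin concentration changes
#' (micromolar). Only HbO is propagated by the pipeline.
#'
#' @param od_760,od_850 Optical-density change series at 760 and 850 nm.
#' @param cfg A [preprocess_config()].
#' @return A tibble with columns `hbo`, `hbr` (micromolar).
#' @export
od_to_hemoglobin <- function(od_760, od_850, cfg = preprocess_config()) {
  stopifnot(length(od_760) == length(od_850))
  ext <- cfg$extinction
  wls <- c(760, 850)
  eps <- as.matrix(ext[match(wls, ext$wavelength_nm), c("hbo", "hbr")])
  path <- cfg$source_detector_distance_cm * cfg$dpf[as.character(wls)]
  a <- eps * path # 2x2: rows wavelengths, cols chromophores
  if (!all(is.finite(a)) || abs(det(a)) < 1e-8 * max(abs(a))^2) {
    nl_abort("Extinction coefficient matrix is singular or near-singular.")
  }
  conc <- t(solve(a, rbind(od_760, od_850))) * 1e6
  tibble::tibble(hbo = conc[, 1], hbr = conc[, 2])
}

# Internal: lag-1 autocorrelation
lag1_autocorr <- function(x) {
  if (stats::sd(x) == 0) nl_abort("Zero-variance series in autocorrelation QC.")
  stats::cor(x[-length(x)], x[-1])
}

#' Autocorrelation-change quality control
#'
#' Gauges the impact of motion correction on a channel: the channel is
#' rejected when the absolute change in lag-1 autocorrelation between the
#' series before and after correction strictly exceeds the threshold.
#'
#' @param pre_series,post_series Series before and after correction.
#' @param cfg A [preprocess_config()].
#' @return List with `keep` (logical) and `delta` (the absolute change).
#' @export
autocorr_change_qc <- function(pre_series, post_series,
                               cfg = preprocess_config()) {
  stopifnot(length(pre_series) == length(post_series))
  delta <- abs(lag1_autocorr(post_series) - lag1_autocorr(pre_series))
  list(keep = delta <= cfg$autocorr_delta_threshold, delta = delta)
}

#' Average retained channels into ROIs and z-score
#'
#' Unweighted mean of the retained channels of each region of interest,
#' then z-scored per participant and ROI.
#'
#' @param hbo Numeric matrix, time by channel (HbO series).
#' @param channel_roi_map Tibble with columns `channel`, `roi`.
#' @param retained Character vector of retained channel names.
#' @return A named list of z-scored ROI series; ROIs with no retained
#'   channel are absent (flagged by the pipeline as missing).
#' @export
average_roi_and_zscore <- function(hbo, channel_roi_map, retained) {
  rois <- unique(channel_roi_map$roi)
  out <- list()
  for (r in rois) {
    chans <- intersect(channel_roi_map$channel[channel_roi_map$roi == r],
                       retained)
    if (length(chans) == 0) next
    avg <- rowMeans(hbo[, chans, drop = FALSE])
    out[[r]] <- as.numeric(scale(avg))
  }
  out
}

#' Resample a series to one sample per second
#'
#' Anti-aliased resampling by averaging over consecutive 1-second bins
#' (or `1/target_fs_hz`-second bins). A recording of `duration_s` seconds
#' yields exactly `floor(duration_s * target_fs_hz)` samples.
#'
#' @param x Numeric series.
#' @param fs_hz Input sampling rate; must be at least the target rate.
#' @param target_fs_hz Output rate (Hz).
#' @return The resampled series.
#' @export
downsample_to_1hz <- function(x, fs_hz, target_fs_hz = 1) {
  if (fs_hz < target_fs_hz) {
    nl_abort("Input sampling rate is below the target rate.")
  }
  n <- length(x)
  len <- floor(n / fs_hz * target_fs_hz)
  bin <- floor((seq_len(n) - 1) / fs_hz * target_fs_hz)
  keep <- bin < len
  as.numeric(tapply(x[keep], bin[keep], mean))
}

#' Full preprocessing pipeline for one recording
#'
#' Stage order: QCD channel rejection, motion-spike removal, bandpass,
#' modified Beer-Lambert conversion, autocorrelation-change QC, ROI
#' averaging with z-scoring, resampling to 1 Hz. Entirely deterministic.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [preprocess_config()].
#' @return A list of class `roi_timeseries_set`: `series` (tibble with
#'   `participant_id`, `roi`, `time_s`, `value`), `qc_log`, `retained`
#'   (channels per ROI), `missing_rois`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  qc <- reject_channels_qcd(rec, cfg)
  retained <- names(qc$mask)[qc$mask]
  qc_log <- qc$qc_log
  hbo <- list()
  for (ch in retained) {
    od_pre <- rec$od[, paste0(ch, "@", rec$wavelengths)]
    sp1 <- remove_motion_spikes(od_pre[, 1], rec$fs_hz, cfg)
    sp2 <- remove_motion_spikes(od_pre[, 2], rec$fs_hz, cfg)
    # autocorrelation change induced by the motion-correction step
    keep <- TRUE
    for (k in 1:2) {
      pre <- od_pre[, k]
      post <- if (k == 1) sp1$series else sp2$series
      if (stats::sd(pre) == 0 || stats::sd(post) == 0) next
      if (!autocorr_change_qc(pre, post, cfg)$keep) keep <- FALSE
    }
    if (!keep) {
      qc_log <- dplyr::bind_rows(qc_log, tibble::tibble(
        channel = ch, stage = "autocorr",
        reason = sprintf("lag-1 autocorrelation change > %g",
                         cfg$autocorr_delta_threshold)
      ))
      next
    }
    f1 <- bandpass_filter(sp1$series, rec$fs_hz, cfg)
    f2 <- bandpass_filter(sp2$series, rec$fs_hz, cfg)
    hb <- od_to_hemoglobin(f1, f2, cfg)
    hbo[[ch]] <- hb$hbo
    if (length(sp1$spike_idx) + length(sp2$spike_idx) > 0) {
      qc_log <- dplyr::bind_rows(qc_log, tibble::tibble(
        channel = ch, stage = "spikes",
        reason = sprintf("%d spike sample(s) interpolated",
                         length(union(sp1$spike_idx, sp2$spike_idx)))
      ))
    }
  }
  surviving <- names(hbo)
  rois <- unique(rec$channel_roi_map$roi)
  if (length(surviving) == 0) {
    return(structure(
      list(series = tibble::tibble(participant_id = character(),
                                   roi = character(), time_s = numeric(),
                                   value = numeric()),
           qc_log = qc_log,
           retained = tibble::tibble(roi = character(),
                                     n_channels_retained = integer()),
           missing_rois = rois),
      class = "roi_timeseries_set"
    ))
  }
  hbo_mat <- do.call(cbind, hbo)
  colnames(hbo_mat) <- surviving
  roi_series <- average_roi_and_zscore(hbo_mat, rec$channel_roi_map, surviving)
  missing <- setdiff(rois, names(roi_series))
  series <- purrr::imap(roi_series, function(v, r) {
    ds <- downsample_to_1hz(v, rec$fs_hz, cfg$target_fs_hz)
    tibble::tibble(participant_id = rec$participant_id, roi = r,
                   time_s = seq_along(ds) - 1, value = ds)
  })
  retained_tbl <- rec$channel_roi_map |>
    dplyr::filter(.data$channel %in% surviving) |>
    dplyr::count(.data$roi, name = "n_channels_retained")
  structure(
    list(series = dplyr::bind_rows(series), qc_log = qc_log,
         retained = retained_tbl, missing_rois = missing),
    class = "roi_timeseries_set"
  )
}

#' Preprocess every recording of a cohort
#'
#' @param cohort A [generate_cohort()] result or any list with a
#'   `recordings` element of [raw_recording()] objects.
#' @param cfg A [preprocess_config()].
#' @return A list of class `preprocessed_cohort`: `series` (long tibble),
#'   `qc_log`, `retained`, `missing` (participant x missing ROI tibble).
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  res <- purrr::map(cohort$recordings, preprocess_recording, cfg = cfg)
  ids <- purrr::map_chr(cohort$recordings, "participant_id")
  missing <- purrr::map2(res, ids, function(r, id) {
    if (length(r$missing_rois) == 0) return(NULL)
    tibble::tibble(participant_id = id, roi = r$missing_rois)
  })
  qc <- purrr::map2(res, ids, function(r, id) {
    if (nrow(r$qc_log) == 0) return(NULL)
    dplyr::mutate(r$qc_log, participant_id = id, .before = 1)
  })
  structure(
    list(
      series = dplyr::bind_rows(purrr::map(res, "series")),
      qc_log = dplyr::bind_rows(qc),
      retained = dplyr::bind_rows(purrr::map2(
        res, ids, ~ dplyr::mutate(.x$retained, participant_id = .y, .before = 1)
      )),
      missing = dplyr::bind_rows(missing)
    ),
    class = "preprocessed_cohort"
  )
}

#' Feature matrix for one ROI
#'
#' Rows are participants, columns are 1-Hz timepoints; participants whose
#' ROI was rejected are absent.
#'
#' @param processed A [preprocess_cohort()] result (or its `series` tibble).
#' @param roi ROI name.
#' @return A numeric matrix with participant ids as row names.
#' @export
feature_matrix <- function(processed, roi) {
  series <- if (inherits(processed, "preprocessed_cohort")) {
    processed$series
  } else {
    processed
  }
  wide <- series |>
    dplyr::filter(.data$roi == !!roi) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "time_s",
                       values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant_id
  m
}
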