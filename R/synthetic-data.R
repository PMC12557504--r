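#' Canonical double-gamma hemodynamic response
#'
#' SPM-style difference of two gamma densities (response peak ~5-6 s,
#' undershoot ~15 s), used to smooth planted group effects so that a
#' second of divergent neural processing appears in the recording with a
#' realistic hemodynamic shape.
#'
#' @param t Time (s), may be negative (returns 0 there).
#' @return Kernel values; unit peak amplitude.
#' @export
hrf_double_gamma <- function(t) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = 6, rate = 1) -
                stats::dgamma(t, shape = 16, rate = 1) / 6)
  h / max(stats::dgamma(0:20, shape = 6, rate = 1))
}

#' Specification of a synthetic fNIRS cohort
#'
#' Defines the study conditions the generator emulates: a two-group
#' cohort watching a shared 10-min-53-s stimulus, recorded at 3.906 Hz
#' at 760/850 nm, whose ROI-level HbO timeseries differ between groups at
#' a known sparse set of stimulus-locked seconds. The planted divergence
#' is hemodynamically smoothed (double-gamma kernel re-centred so its
#' peak falls on the planted second) and calibrated so the group mean
#' difference at a planted second equals `effect_size` between-subject
#' standard deviations on the 1-Hz ROI-averaged scale. Channel series are
#' contaminated with baseline drift, cardiac (~1 Hz) and respiratory
#' (~0.3 Hz) oscillations, white noise, motion spikes, and occasional
#' saturated channels.
#'
#' @param n_participants Number of participants.
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Stimulus length (s).
#' @param n_channels Channels per ROI.
#' @param roi_names ROI names.
#' @param planted_timepoints Second indices (0-based, within
#'   `[0, duration_s)`) where the group means diverge.
#' @param planted_roi ROI carrying the planted effect.
#' @param planted_measure Outcome measure tied to the true grouping.
#' @param measures Outcome measure names.
#' @param effect_size Standardized group mean difference at planted
#'   seconds (between-subject SD units).
#' @param noise Named list of amplitudes: `shared` and `subject`
#'   (micromolar SD of the stimulus-driven and idiosyncratic HbO
#'   components), `white` (micromolar SD of channel white noise),
#'   `cardiac`, `respiratory` (micromolar oscillation amplitudes),
#'   `drift` (optical-density drift amplitude).
#' @param spike_rate Expected motion spikes per participant.
#' @param bad_channel_prob Probability a channel is saturated/noisy.
#' @param likert Named list: `low_mode`, `high_mode`, `dispersion` of the
#'   bimodal Likert generator for the planted measure.
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 68,
                        fs_hz = 3.906,
                        duration_s = 653,
                        n_channels = 4,
                        roi_names = c("TPJ", "dmPFC", "amPFC"),
                        planted_timepoints = integer(0),
                        planted_roi = roi_names[1],
                        planted_measure = measures[1],
                        measures = c("overwhelmed", "challenge", "burnout"),
                        effect_size = 0,
                        noise = list(shared = 0.3, subject = 0.6,
                                     white = 0.3, cardiac = 0.25,
                                     respiratory = 0.15, drift = 0.05),
                        spike_rate = 3,
                        bad_channel_prob = 0.05,
                        likert = list(low_mode = 2, high_mode = 6,
                                      dispersion = 1),
                        seed = 1L) {
  check_positive(n_participants, "n_participants")
  check_positive(duration_s, "duration_s")
  check_positive(fs_hz, "fs_hz")
  check_positive(n_channels, "n_channels")
  check_prob(bad_channel_prob, "bad_channel_prob")
  if (!is.numeric(effect_size) || effect_size < 0) {
    nl_abort("`effect_size` must be non-negative.")
  }
  planted_timepoints <- as.integer(planted_timepoints)
  if (length(planted_timepoints) > 0 &&
      (min(planted_timepoints) < 0 || max(planted_timepoints) >= duration_s)) {
    nl_abort("`planted_timepoints` must lie within [0, duration_s).")
  }
  if (!planted_roi %in% roi_names) nl_abort("`planted_roi` not in `roi_names`.")
  structure(
    list(n_participants = as.integer(n_participants), fs_hz = fs_hz,
         duration_s = duration_s, n_channels = as.integer(n_channels),
         roi_names = roi_names, planted_timepoints = planted_timepoints,
         planted_roi = planted_roi, planted_measure = planted_measure,
         measures = measures, effect_size = effect_size, noise = noise,
         spike_rate = spike_rate, bad_channel_prob = bad_channel_prob,
         likert = likert, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Internal: smooth band-limited noise (SD-normalized), by low-pass
# filtering white noise with a moving double-exponential smoother.
smooth_noise <- function(n, fs_hz, sd_target, cutoff_hz = 0.1) {
  if (sd_target == 0) return(numeric(n))
  x <- stats::rnorm(n + 200)
  alpha <- 2 * pi * cutoff_hz / fs_hz
  alpha <- alpha / (1 + alpha)
  y <- stats::filter(x, alpha, method = "recursive", init = 0)
  y <- rev(as.numeric(stats::filter(rev(as.numeric(y)), alpha,
                                    method = "recursive", init = 0)))
  y <- y[101:(100 + n)]
  y <- y - mean(y)
  y / stats::sd(y) * sd_target
}

# Internal: planted group-difference time course at fs_hz, unit peak.
# The double-gamma kernel is re-centred so its peak coincides with each
# planted second.
planted_course <- function(planted_timepoints, duration_s, fs_hz) {
  t <- (seq_len(ceiling(duration_s * fs_hz)) - 1) / fs_hz
  if (length(planted_timepoints) == 0) return(numeric(length(t)))
  peak <- 5 # double-gamma mode (s)
  e <- numeric(length(t))
  for (tk in planted_timepoints) {
    e <- e + hrf_double_gamma(t - tk + peak)
  }
  e / max(abs(e))
}

#' Generate a synthetic two-group cohort
#'
#' Builds per-participant dual-wavelength optical-density recordings from
#' latent HbO/HbR concentration timeseries via the forward Beer-Lambert
#' model, so the downstream inversion is exercised end-to-end. The cohort
#' carries its ground truth: group labels, planted timepoints, a latent
#' noise-free-channel 1-Hz ROI reference, bimodal Likert responses for
#' each outcome measure (only the planted measure is tied to the true
#' grouping) and per-second theme tracks, one of which overlaps the
#' planted seconds shifted 3 s earlier (stimulus time).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `recordings`,
#'   `true_group`, `planted_timepoints`, `theme_tracks`, `likert`,
#'   `latent_roi`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  fs <- spec$fs_hz
  nsamp <- ceiling(spec$duration_s * fs)
  t <- (seq_len(nsamp) - 1) / fs
  nz <- spec$noise
  rois <- spec$roi_names
  np <- spec$n_participants
  ext <- extinction_coefficients()
  dpf <- 6
  dist <- 3
  a_mat <- as.matrix(ext[, c("hbo", "hbr")]) * dist * dpf * 1e-6 # per uM
  baseline <- c(`760` = 0.5, `850` = 0.6)

  true_group <- rep(c(0L, 1L), length.out = np)
  true_group <- sample(true_group)

  shared <- lapply(rois, function(r) smooth_noise(nsamp, fs, nz$shared))
  names(shared) <- rois
  eff <- planted_course(spec$planted_timepoints, spec$duration_s, fs) *
    spec$effect_size * nz$subject

  recordings <- vector("list", np)
  latent <- list()
  for (i in seq_len(np)) {
    pid <- sprintf("P%03d", i)
    gsign <- if (true_group[i] == 1L) 0.5 else -0.5
    od_cols <- list()
    chmap <- list()
    for (r in rois) {
      subj <- smooth_noise(nsamp, fs, nz$subject)
      hbo_latent <- shared[[r]] + subj +
        (if (r == spec$planted_roi) gsign * eff else 0)
      hbr_latent <- -0.5 * hbo_latent + smooth_noise(nsamp, fs, 0.2 * nz$subject)
      latent[[paste(pid, r)]] <- tibble::tibble(
        participant_id = pid, roi = r,
        time_s = seq_len(floor(spec$duration_s)) - 1,
        value = downsample_to_1hz(hbo_latent, fs)
      )
      for (k in seq_len(spec$n_channels)) {
        ch <- paste0(r, "_", k)
        chmap[[ch]] <- r
        bad <- stats::runif(1) < spec$bad_channel_prob
        if (bad) {
          for (wl in c("760", "850")) {
            od <- 0.05 + stats::rnorm(nsamp, 0, 0.005)
            nburst <- sample(2:4, 1)
            for (b in seq_len(nburst)) {
              len <- round(stats::runif(1, 2.5, 6) * fs)
              start <- sample.int(nsamp - len, 1)
              od[start:(start + len - 1)] <- od[start:(start + len - 1)] +
                stats::runif(len, -1, 1)
            }
            od_cols[[paste0(ch, "@", wl)]] <- od
          }
          next
        }
        hbo_ch <- hbo_latent + stats::rnorm(nsamp, 0, nz$white) +
          nz$cardiac * sin(2 * pi * stats::rnorm(1, 1.0, 0.03) * t +
                             stats::runif(1, 0, 2 * pi)) +
          nz$respiratory * sin(2 * pi * stats::rnorm(1, 0.3, 0.02) * t +
                                 stats::runif(1, 0, 2 * pi))
        hbr_ch <- hbr_latent + stats::rnorm(nsamp, 0, 0.5 * nz$white)
        od_pair <- cbind(hbo_ch, hbr_ch) %*% t(a_mat)
        for (w in 1:2) {
          wl <- c("760", "850")[w]
          drift <- nz$drift * sin(2 * pi * stats::runif(1, 0.001, 0.003) * t +
                                    stats::runif(1, 0, 2 * pi)) +
            nz$drift * (t / max(t) - 0.5) * stats::rnorm(1)
          od_cols[[paste0(ch, "@", wl)]] <-
            baseline[wl] + od_pair[, w] + drift +
            stats::rnorm(nsamp, 0, 0.0015)
        }
      }
    }
    od <- do.call(cbind, od_cols)
    # motion spikes: participant-level events, each hitting a random
    # subset of channels (head movement rarely disturbs every optode
    # equally); amplitudes are kept moderate so isolated interpolated
    # spikes do not by themselves flip the autocorrelation QC
    n_spikes <- stats::rpois(1, spec$spike_rate)
    if (n_spikes > 0) {
      for (sidx in seq_len(n_spikes)) {
        pos <- sample.int(nsamp - 3, 1)
        width <- sample(1:2, 1)
        hit <- stats::runif(ncol(od)) < 0.5
        hit[sample.int(ncol(od), 1)] <- TRUE
        for (j in which(hit)) {
          amp <- stats::sd(od[, j]) * stats::runif(1, 6, 9) *
            sample(c(-1, 1), 1)
          od[pos:(pos + width - 1), j] <- od[pos:(pos + width - 1), j] + amp
        }
      }
    }
    recordings[[i]] <- raw_recording(
      participant_id = pid, fs_hz = fs, od = od,
      channel_roi_map = tibble::tibble(channel = names(chmap),
                                       roi = unlist(chmap))
    )
  }

  likert <- purrr::map(seq_along(spec$measures), function(m) {
    meas <- spec$measures[m]
    grp <- if (meas == spec$planted_measure) {
      true_group
    } else {
      sample(rep(c(0L, 1L), length.out = np))
    }
    tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(np)),
      measure = meas,
      response = generate_likert(grp, spec$likert$low_mode,
                                 spec$likert$high_mode,
                                 spec$likert$dispersion,
                                 seed = derive_seed(spec$seed, 7000 + m))
    )
  })

  theme_tracks <- generate_cohort_themes(spec)

  structure(
    list(recordings = recordings, true_group = true_group,
         planted_timepoints = spec$planted_timepoints,
         theme_tracks = theme_tracks,
         likert = dplyr::bind_rows(likert),
         latent_roi = dplyr::bind_rows(latent),
         spec = spec),
    class = "synthetic_cohort"
  )
}

# Internal: theme tracks for a cohort. The "signal" theme covers the
# planted seconds shifted 3 s earlier (stimulus time precedes the
# hemodynamic response); the remaining themes are random intervals at
# 10-20% coverage.
generate_cohort_themes <- function(spec) {
  dur <- floor(spec$duration_s)
  themes <- c("signal_theme", "reward", "anecdote", "social")
  tracks <- list(time_s = seq_len(dur) - 1)
  if (length(spec$planted_timepoints) > 0) {
    iv <- cbind(pmax(0, spec$planted_timepoints - 3),
                pmax(1, spec$planted_timepoints - 3 + 2))
    tracks[["signal_theme"]] <- generate_theme_track(dur, iv)
  } else {
    tracks[["signal_theme"]] <- generate_theme_track(
      dur, random_event_intervals(dur, 6, 15,
                                  seed = derive_seed(spec$seed, 8001)))
  }
  for (j in 2:4) {
    tracks[[themes[j]]] <- generate_theme_track(
      dur, random_event_intervals(dur, 7, 14,
                                  seed = derive_seed(spec$seed, 8000 + j)))
  }
  tibble::as_tibble(tracks)
}

#' Random non-overlapping stimulus event intervals
#'
#' @param duration_s Track length (s).
#' @param n_events Number of intervals to draw.
#' @param mean_length_s Mean interval length (s).
#' @param seed Seed.
#' @return Matrix with columns start, end (half-open seconds).
#' @export
random_event_intervals <- function(duration_s, n_events, mean_length_s = 12,
                                   seed = 1L) {
  with_seed(seed, {
    lens <- pmin(max(2, floor(duration_s / 3)),
                 pmax(2, round(stats::rexp(n_events, 1 / mean_length_s))))
    span <- max(1, duration_s - max(lens) - 1)
    n_events <- min(n_events, span)
    lens <- lens[seq_len(n_events)]
    starts <- sort(sample.int(span, n_events))
    iv <- cbind(starts, pmin(duration_s, starts + lens))
    # merge overlaps
    if (n_events > 1) {
      for (i in 2:n_events) {
        if (iv[i, 1] < iv[i - 1, 2]) iv[i, 1] <- iv[i - 1, 2]
      }
      iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
    }
    iv
  })
}

#' Binary per-second theme-annotation track
#'
#' Marks, for every second of the stimulus, whether a theme is present:
#' 1 exactly inside the given half-open `[start, end)` intervals.
#' Overlapping intervals are merged.
#'
#' @param duration_s Track length (s).
#' @param event_intervals Matrix or list of `[start, end)` second spans.
#' @return Integer 0/1 vector of length `duration_s`.
#' @export
generate_theme_track <- function(duration_s, event_intervals) {
  check_positive(duration_s, "duration_s")
  track <- integer(duration_s)
  if (is.list(event_intervals)) {
    event_intervals <- do.call(rbind, event_intervals)
  }
  if (is.null(event_intervals) || length(event_intervals) == 0) return(track)
  for (i in seq_len(nrow(event_intervals))) {
    s <- event_intervals[i, 1]
    e <- event_intervals[i, 2]
    if (s < 0 || e > duration_s || s >= e) {
      nl_abort("Event interval out of range [0, duration_s).")
    }
    track[(s + 1):e] <- 1L
  }
  track
}

#' Bimodal Likert responses for a labelled cohort
#'
#' Group-0 responses cluster at `low_mode`, group-1 at `high_mode`;
#' responses are rounded Gaussian draws clipped to the 1-7 scale,
#' emulating the bimodal outcome distributions of a two-lens cohort.
#'
#' @param true_group Integer 0/1 labels.
#' @param low_mode,high_mode Group modes on the 1-7 scale.
#' @param dispersion Gaussian SD before rounding.
#' @param seed Seed.
#' @return Integer responses in 1..7.
#' @export
generate_likert <- function(true_group, low_mode = 2, high_mode = 6,
                            dispersion = 1, seed = 1L) {
  if (low_mode < 1 || low_mode > 7 || high_mode < 1 || high_mode > 7) {
    nl_abort("Modes must lie on the 1-7 scale.")
  }
  with_seed(seed, {
    mu <- ifelse(true_group == 1L, high_mode, low_mode)
    r <- round(stats::rnorm(length(true_group), mu, dispersion))
    as.integer(pmin(7, pmax(1, r)))
  })
}
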