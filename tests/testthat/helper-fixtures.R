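# Small reusable fixtures, built in code at test time.

# A quiet raw recording: positive optical-density baseline plus smooth
# in-band fluctuations, no spikes, no bad channels.
make_clean_recording <- function(fs_hz = 3.906, duration_s = 80,
                                 n_channels = 2,
                                 rois = c("TPJ", "dmPFC", "amPFC"),
                                 seed = 1) {
  set.seed(seed)
  n <- ceiling(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  cols <- list()
  chmap <- list()
  for (r in rois) {
    for (k in seq_len(n_channels)) {
      ch <- paste0(r, "_", k)
      chmap[[ch]] <- r
      base_sig <- 0.02 * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi)) +
        0.005 * rnorm(n)
      cols[[paste0(ch, "@760")]] <- 0.5 + base_sig
      cols[[paste0(ch, "@850")]] <- 0.6 + 0.8 * base_sig + 0.003 * rnorm(n)
    }
  }
  raw_recording("P001", fs_hz, do.call(cbind, cols),
                tibble::tibble(channel = names(chmap), roi = unlist(chmap)))
}

# Tiny toy classification problem: clear signal in one timepoint.
make_separable_toy <- function(n = 8, p = 5, signal_col = 2, seed = 1,
                               gap = 6) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p, sd = 0.5), n, p)
  X[, signal_col] <- X[, signal_col] + gap * y
  list(X = X, y = y)
}

cohort_ids <- function(cohort) {
  vapply(cohort$recordings, function(r) r$participant_id, character(1))
}

# Three (roi, measure) pairs: one with a strong planted signal, two null.
make_pair_datasets <- function() {
  set.seed(30)
  n <- 8
  y1 <- rep(c(0L, 1L), each = 4)
  X_sig <- matrix(rnorm(n * 6, sd = 0.4), n, 6)
  X_sig[, 2] <- X_sig[, 2] + 6 * y1
  X_null1 <- matrix(rnorm(n * 6), n, 6)
  X_null2 <- matrix(rnorm(n * 6), n, 6)
  y2 <- rep(c(1L, 0L), each = 4)
  list(
    "TPJ.m1" = list(roi = "TPJ", measure = "m1", X = X_sig, y = y1),
    "dmPFC.m1" = list(roi = "dmPFC", measure = "m1", X = X_null1, y = y1),
    "TPJ.m2" = list(roi = "TPJ", measure = "m2", X = X_null2, y = y2)
  )
}

# Feature matrix + aligned labels for one ROI of a synthetic cohort.
roi_dataset <- function(cohort, processed, roi) {
  X <- feature_matrix(processed, roi)
  ids <- rownames(X)
  g <- cohort$true_group[match(ids, cohort_ids(cohort))]
  list(X = X, y = g)
}
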