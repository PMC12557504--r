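test_that("the QCD cutoff follows the sampling-rate formula", {
  expect_equal(compute_cthresh(3.906), 0.48282)
  expect_equal(compute_cthresh(0), 0.6)
  expect_equal(compute_cthresh(20), 0) # floored
  expect_error(compute_cthresh(-1), "non-negative")
})

test_that("sliding QCD matches the brute-force oracle on both code paths", {
  set.seed(42)
  # fast path: 3-sample windows at the acquisition rate
  x1 <- 0.5 + 0.05 * rnorm(500)
  x1[200:240] <- x1[200:240] + runif(41, -1, 1) # dispersion burst
  expect_equal(sliding_qcd(x1, 3.906, 1), oracle_sliding_qcd(x1, 3.906, 1))
  # generic path: wider windows at a higher rate
  x2 <- 1 + 0.1 * rnorm(800)
  expect_equal(sliding_qcd(x2, 10, 1), oracle_sliding_qcd(x2, 10, 1))
  expect_equal(sliding_qcd(x2, 3.906, 4), oracle_sliding_qcd(x2, 3.906, 4))
})

make_burst_recording <- function(burst_s, fs = 3.906, duration = 60,
                                 seed = 5) {
  set.seed(seed)
  n <- ceiling(duration * fs)
  clean <- function() 0.5 + 0.01 * rnorm(n)
  burst <- clean()
  if (burst_s > 0) {
    len <- round(burst_s * fs)
    burst[100:(100 + len - 1)] <- burst[100:(100 + len - 1)] +
      runif(len, -1.5, 1.5)
  }
  od <- cbind(`A_1@760` = burst, `A_1@850` = clean(),
              `A_2@760` = clean(), `A_2@850` = clean())
  raw_recording("P001", fs, od,
                tibble::tibble(channel = c("A_1", "A_2"), roi = "A"))
}

test_that("QCD rejection honours the 2-second persistence rule", {
  # constant channel: QCD identically zero, retained
  n <- 235
  od <- cbind(`A_1@760` = rep(0.7, n), `A_1@850` = rep(0.7, n))
  rec <- raw_recording("P001", 3.906, od,
                       tibble::tibble(channel = "A_1", roi = "A"))
  expect_true(all(sliding_qcd(od[, 1], 3.906, 1) == 0))
  expect_true(reject_channels_qcd(rec)$mask[["A_1"]])

  long_burst <- reject_channels_qcd(make_burst_recording(3))
  expect_false(long_burst$mask[["A_1"]])
  expect_true(long_burst$mask[["A_2"]])
  expect_match(long_burst$qc_log$reason[1], "QCD")

  short_burst <- reject_channels_qcd(make_burst_recording(1))
  expect_true(all(short_burst$mask))
})

test_that("motion-spike removal flags and repairs fast large excursions", {
  cfg <- preprocess_config()
  set.seed(8)
  # near-flat series with one displaced sample
  x <- rnorm(400, sd = 1)
  x[200] <- x[200] + 8 * sd(x)
  out <- remove_motion_spikes(x, 3.906, cfg)
  expect_true(200 %in% out$spike_idx)
  expect_lt(abs(out$series[200] - (x[199] + x[201]) / 2), 1e-9)
  # a 4-SD displacement stays untouched
  y <- rnorm(400, sd = 1)
  y[200] <- y[200] + 4 * sd(y)
  expect_false(200 %in% remove_motion_spikes(y, 3.906, cfg)$spike_idx)
  # constant series: nothing to flag
  expect_identical(remove_motion_spikes(rep(2, 100), 3.906, cfg)$spike_idx,
                   integer(0))
})

test_that("spike flags match the brute-force oracle and recover implants", {
  cfg <- preprocess_config()
  set.seed(9)
  x <- rnorm(3000)
  truth <- c(400, 900, 1500, 2100, 2700)
  for (pos in truth) x[pos] <- x[pos] + sample(c(-1, 1), 1) * 9
  out <- remove_motion_spikes(x, 3.906, cfg)
  expect_identical(out$spike_idx, oracle_spike_flags(x, 3.906))
  expect_true(all(truth %in% out$spike_idx))
  false_pos <- setdiff(out$spike_idx, c(truth - 1, truth, truth + 1))
  expect_lte(length(false_pos), length(x) / 1000)
  # oracle equivalence on a second regime: higher rate, wider windows
  z <- rnorm(2000)
  z[700] <- z[700] + 12
  out2 <- remove_motion_spikes(z, 10, cfg)
  expect_identical(out2$spike_idx, oracle_spike_flags(z, 10))
})

test_that("the bandpass passes the band and rejects drift and physiology", {
  fs <- 3.906
  cfg <- preprocess_config()
  t <- seq(0, 652.9, by = 1 / fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  # DC offset is removed
  dc <- bandpass_filter(rep(5, length(t)), fs, cfg)
  expect_lt(max(abs(dc)), 1e-3)
  # cardiac-band tone attenuated at least 10x
  cardiac <- bandpass_filter(sin(2 * pi * 1.0 * t + 0.7), fs, cfg)
  expect_lt(diff(range(cardiac)) / 2, 0.1)
  # in-band tone retained at least 90%
  slow <- bandpass_filter(sin(2 * pi * 0.05 * t + 0.3), fs, cfg)
  expect_gt(diff(range(slow[mid])) / 2, 0.9)
  # sub-band drift attenuated at least 10x
  drift <- bandpass_filter(sin(2 * pi * 0.001 * t), fs, cfg)
  expect_lt(diff(range(drift)) / 2, 0.1)
  expect_error(bandpass_filter(rnorm(10), fs, cfg), "short")
})

test_that("Beer-Lambert inversion is exact on forward-simulated data", {
  cfg <- preprocess_config()
  expect_equal(od_to_hemoglobin(rep(0, 5), rep(0, 5), cfg)$hbo, rep(0, 5))
  set.seed(10)
  hbo <- rnorm(300, sd = 0.5)
  hbr <- rnorm(300, sd = 0.3)
  ext <- extinction_coefficients()
  a <- as.matrix(ext[, c("hbo", "hbr")]) *
    cfg$source_detector_distance_cm * cfg$dpf * 1e-6
  od <- cbind(hbo, hbr) %*% t(a)
  out <- od_to_hemoglobin(od[, 1], od[, 2], cfg)
  expect_lt(max(abs(out$hbo - hbo)), 1e-10)
  expect_lt(max(abs(out$hbr - hbr)), 1e-10)
  # proportional extinction rows are singular
  bad_cfg <- cfg
  bad_cfg$extinction <- tibble::tibble(wavelength_nm = c(760, 850),
                                       hbo = c(1000, 2000),
                                       hbr = c(1500, 3000))
  expect_error(od_to_hemoglobin(od[, 1], od[, 2], bad_cfg), "singular")
})

test_that("autocorrelation-change QC rejects restructured channels only", {
  cfg <- preprocess_config()
  set.seed(11)
  x <- rnorm(1000)
  expect_true(autocorr_change_qc(x, x, cfg)$keep)
  smoothed <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  smoothed[is.na(smoothed)] <- 0
  res <- autocorr_change_qc(x, as.numeric(smoothed), cfg)
  expect_false(res$keep)
  # oracle: lag-1 autocorrelation from its definition
  rho <- function(v) cor(v[-length(v)], v[-1])
  expect_equal(res$delta, abs(rho(as.numeric(smoothed)) - rho(x)))
  # boundary is strict: a change equal to the threshold is kept
  cfg_edge <- cfg
  cfg_edge$autocorr_delta_threshold <- res$delta
  expect_true(autocorr_change_qc(x, as.numeric(smoothed), cfg_edge)$keep)
  expect_error(autocorr_change_qc(rep(1, 10), rep(1, 10), cfg), "variance")
})

test_that("ROI averaging uses retained channels and z-scores the result", {
  set.seed(12)
  n <- 200
  ch <- matrix(rnorm(3 * n), n, 3,
               dimnames = list(NULL, c("A_1", "A_2", "A_3")))
  map <- tibble::tibble(channel = colnames(ch), roi = "A")
  # two identical channels: average equals either channel (then z-scored)
  twin <- cbind(A_1 = ch[, 1], A_2 = ch[, 1])
  out <- average_roi_and_zscore(twin, map[1:2, ], c("A_1", "A_2"))
  expect_equal(out$A, as.numeric(scale(ch[, 1])))
  expect_lt(abs(mean(out$A)), 1e-6)
  expect_lt(abs(sd(out$A) - 1), 1e-6)
  # one channel rejected: average over the remaining two, by hand
  out2 <- average_roi_and_zscore(ch, map, c("A_1", "A_3"))
  expect_equal(out2$A, as.numeric(scale((ch[, 1] + ch[, 3]) / 2)))
  # empty ROI is absent from the output
  expect_null(average_roi_and_zscore(ch, map, character(0))$A)
})

test_that("1-Hz resampling yields one sample per stimulus second", {
  fs <- 3.906
  x <- rnorm(ceiling(653 * fs))
  expect_length(downsample_to_1hz(x, fs), 653)
  expect_equal(downsample_to_1hz(rep(3.3, 100), 3.906), rep(3.3, 25))
  # a 1-s boxcar at second 100 peaks at output index 100 (0-based)
  n <- ceiling(653 * fs)
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= 100 & t < 101)
  ds <- downsample_to_1hz(box, fs)
  expect_equal(which.max(ds) - 1, 100)
  expect_error(downsample_to_1hz(rnorm(10), 0.5), "below")
})

test_that("the full pipeline keeps clean ROIs and drops saturated ones", {
  rec <- make_clean_recording(duration_s = 653)
  out <- preprocess_recording(rec)
  expect_setequal(unique(out$series$roi), c("TPJ", "dmPFC", "amPFC"))
  expect_true(all(table(out$series$roi) == 653))
  expect_length(out$missing_rois, 0)
  # per-ROI z-scoring holds before resampling artifacts: the 1-Hz series
  # stays near zero mean / unit scale
  per_roi <- split(out$series$value, out$series$roi)
  for (v in per_roi) expect_lt(abs(mean(v)), 0.05)

  # saturate every channel of one ROI
  rec2 <- make_clean_recording(duration_s = 60)
  set.seed(13)
  for (ch in c("TPJ_1", "TPJ_2")) {
    for (wl in c("@760", "@850")) {
      col <- paste0(ch, wl)
      n <- nrow(rec2$od)
      bad <- 0.05 + rnorm(n, 0, 0.005)
      bad[50:120] <- bad[50:120] + runif(71, -1, 1)
      rec2$od[, col] <- bad
    }
  }
  out2 <- preprocess_recording(rec2)
  expect_identical(out2$missing_rois, "TPJ")
  expect_setequal(unique(out2$series$roi), c("dmPFC", "amPFC"))
})

test_that("preprocessing is deterministic and its stage order is pinned", {
  rec <- make_clean_recording(duration_s = 60, seed = 3)
  # inject a spike so the spike stage is active
  rec$od[100, "TPJ_1@760"] <- rec$od[100, "TPJ_1@760"] + 0.5
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$series, b$series)
  # spike removal must precede the bandpass: interpolating the raw spike
  # and filtering differs from filtering first (the filter smears the
  # spike below threshold)
  cfg <- preprocess_config()
  x <- rec$od[, "TPJ_1@760"]
  pipeline_order <- bandpass_filter(
    remove_motion_spikes(x, rec$fs_hz, cfg)$series, rec$fs_hz, cfg)
  swapped <- remove_motion_spikes(
    bandpass_filter(x, rec$fs_hz, cfg), rec$fs_hz, cfg)$series
  expect_gt(max(abs(pipeline_order - swapped)), 1e-6)
})
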