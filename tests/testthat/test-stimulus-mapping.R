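test_that("top and never-selected sets partition by selection frequency", {
  freq <- rep(0, 100)
  freq[11:35] <- runif(25, 0.2, 1)
  sets <- top_and_never_selected(freq, stimulus_map_config(top_k = 25))
  expect_identical(sets$top, 10:34)
  expect_identical(sets$never, c(0:9, 35:99))
  expect_length(intersect(sets$top, sets$never), 0)

  # all-zero frequencies: empty top with a warning
  expect_warning(sets0 <- top_and_never_selected(rep(0, 20),
                                                 stimulus_map_config()),
                 "Only 0")
  expect_length(sets0$top, 0)
  expect_identical(sets0$never, 0:19)
})

test_that("ties at the cutoff resolve to the earliest timepoints", {
  freq <- c(rep(0.5, 10), rep(0.2, 20), rep(0, 70))
  cfg <- stimulus_map_config(top_k = 15)
  sets <- top_and_never_selected(freq, cfg)
  # ten clear winners plus the five earliest of the tied 0.2 block
  expect_identical(sets$top, c(0:9, 10:14))
  # deterministic: same vector, same answer every time
  expect_identical(sets, top_and_never_selected(freq, cfg))
})

test_that("the hemodynamic lag maps neural time onto stimulus time", {
  expect_identical(apply_lag(c(10, 20), 3), c(7, 17))
  expect_identical(apply_lag(c(1), 3), numeric(0))
  expect_identical(apply_lag(c(0, 5, 9), 0), c(0, 5, 9))
})

test_that("odds ratios come out of the 2x2 table as printed", {
  # a=10, b=15, c=10, d=90 -> OR = (10*90)/(15*10) = 6
  track <- integer(125)
  track[1:10] <- 1L      # seconds 0..9: theme, inside top
  track[26:35] <- 1L     # seconds 25..34: theme, inside never
  top <- 0:24
  never <- 25:124
  res <- theme_odds_ratio(top, never, track)
  expect_equal(res$odds_ratio, 6)
  expect_equal(unname(res$table["theme", ]), c(10, 10))

  # equal theme proportions give OR = 1
  track2 <- integer(40)
  track2[c(1:5, 21:25)] <- 1L
  res2 <- theme_odds_ratio(0:19, 20:39, track2)
  expect_equal(res2$odds_ratio, 1)

  expect_error(theme_odds_ratio(integer(0), 0:10, track2), "non-empty")
  expect_error(theme_odds_ratio(0:5, 3:10, track2), "disjoint")
})

test_that("zero cells get the additive correction", {
  track <- integer(30)
  track[1:5] <- 1L # theme only within top
  res <- theme_odds_ratio(0:9, 10:29, track)
  # a=5, b=5, c=0, d=20 -> corrected (5.5*20.5)/(5.5*0.5)
  expect_equal(res$odds_ratio, (5.5 * 20.5) / (5.5 * 0.5))
  expect_equal(unname(res$table[, "never"]), c(0, 20))
})

test_that("odds ratios match the brute-force counter on fuzzed cases", {
  set.seed(33)
  for (k in 1:100) {
    dur <- sample(40:200, 1)
    pts <- sample(0:(dur - 1))
    n_top <- sample(5:15, 1)
    n_nev <- sample(10:(dur - n_top - 5), 1)
    top <- pts[seq_len(n_top)]
    never <- pts[n_top + seq_len(n_nev)]
    track <- rbinom(dur, 1, runif(1, 0.05, 0.6))
    mine <- theme_odds_ratio(top, never, track)$odds_ratio
    expect_equal(mine, oracle_odds_ratio(top, never, track))
  }
})

test_that("circle-shift inference is degenerate-safe and deterministic", {
  cfg <- stimulus_map_config(n_shifts = 500, seed = 7)
  # all-ones track: no rotation can weaken the (vacuous) association,
  # so every null odds ratio is at least the observed one and p = 1
  res <- circle_shift_test(5:9, c(0:4, 20:39), rep(1L, 40), cfg)
  expect_equal(res$p_value, 1)
  expect_true(all(res$null_odds_ratios >= res$odds_ratio))

  set.seed(8)
  track <- rbinom(120, 1, 0.2)
  a <- circle_shift_test(10:19, 40:99, track, cfg)
  b <- circle_shift_test(10:19, 40:99, track, cfg)
  expect_identical(a$null_odds_ratios, b$null_odds_ratios)
  expect_equal(a$p_value, b$p_value)
})

test_that("a top set nested inside a rare theme is detected", {
  track <- integer(300)
  track[101:112] <- 1L # rare theme: seconds 100..111
  top <- 100:111
  never <- setdiff(0:299, 95:120)
  cfg <- stimulus_map_config(n_shifts = 2000, seed = 11)
  res <- circle_shift_test(top, never, track, cfg)
  expect_gt(res$odds_ratio, 10)
  expect_lt(res$p_value, 0.05)
})

test_that("theme mapping produces one tested row per theme", {
  set.seed(12)
  freq <- c(rep(0, 40), runif(30, 0.1, 1), rep(0, 50))
  tracks <- tibble::tibble(
    time_s = 0:119,
    social = rbinom(120, 1, 0.2),
    reward = rbinom(120, 1, 0.15)
  )
  cfg <- stimulus_map_config(top_k = 10, lag_s = 3, n_shifts = 300, seed = 2)
  out <- map_stimulus_themes(freq, tracks, cfg)
  expect_identical(out$theme, c("social", "reward"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_true(all(out$odds_ratio > 0))
  expect_equal(out$theme_in_top + out$no_theme_in_top, c(10, 10))
})
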