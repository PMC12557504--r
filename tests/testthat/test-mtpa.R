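test_that("elastic-net selection finds a perfectly separating timepoint", {
  set.seed(20)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 100), n, 100)
  X[, 3] <- y * 4 + rnorm(n, sd = 0.2)
  sel <- elastic_net_select(X, y, mtpa_config(), seed = 1)
  expect_true(3 %in% sel)
  expect_error(elastic_net_select(X, rep(1L, n), mtpa_config()), "constant")
})

test_that("selection under pure noise stays sparse on average", {
  counts <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 100), 40, 100)
    y <- rep(c(0L, 1L), each = 20)
    length(elastic_net_select(X, y, mtpa_config(), seed = s))
  }, numeric(1))
  expect_lt(mean(counts), 5)
})

test_that("a constant column is admissible but never selected", {
  set.seed(21)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c(0L, 1L), each = 15)
  X[, 4] <- 2.5
  X[, 7] <- y * 3 + rnorm(30, sd = 0.3)
  sel <- elastic_net_select(X, y, mtpa_config(), seed = 2)
  expect_false(4 %in% sel)
})

test_that("the logistic refit matches a numerical-optimization oracle", {
  set.seed(22)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n))
  eta <- -0.5 + 1.3 * X[, 1] - 0.8 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  ridge <- 1e-6
  fit <- fit_selected_logistic(X, y, ridge = ridge)
  # oracle: direct penalized likelihood maximization
  nll <- function(b) {
    e <- b[1] + X %*% b[-1]
    sum(log1p(exp(e))) - sum(y * e) + ridge / 2 * sum(b[-1]^2)
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_lt(max(abs(c(fit$intercept, fit$coef) - opt$par)), 1e-4)
})

test_that("the refit separates separable data and survives separation", {
  toy <- make_separable_toy(n = 10, p = 1, signal_col = 1, gap = 8)
  fit <- fit_selected_logistic(toy$X, toy$y)
  expect_equal(predict(fit, toy$X), toy$y)
})

test_that("zero selected features fall back to a chance-level classifier", {
  fit <- fit_selected_logistic(matrix(nrow = 8, ncol = 0),
                               rep(c(0L, 1L), 4))
  expect_equal(fit$type, "intercept")
  preds <- vapply(1:200, function(s) {
    predict(fit, matrix(0, 1, 0), tie_seed = s)
  }, integer(1))
  expect_gt(mean(preds), 0.3)
  expect_lt(mean(preds), 0.7)
  # an imbalanced (non-upsampled) training fold predicts its majority
  fit2 <- fit_selected_logistic(matrix(nrow = 6, ncol = 0),
                                c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(predict(fit2, matrix(0, 1, 0)), 1L)
})

test_that("LOOCV is perfect on a separable toy and exact in aggregation", {
  toy <- make_separable_toy(n = 8, p = 5, signal_col = 2, gap = 8)
  res <- loocv_mtpa(toy$X, toy$y, mtpa_config(), seed = 3)
  expect_equal(res$accuracy, 1)
  expect_equal(res$accuracy, mean(res$correct))
  expect_true(all(res$correct %in% c(0L, 1L)))
})

test_that("LOOCV-MTPA equals the independently coded nested-loop oracle", {
  set.seed(23)
  n <- 8
  y <- rep(c(0L, 1L), each = 4)
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 2] <- X[, 2] + 1.5 * y # moderate, not trivially separable
  cfg <- mtpa_config(n_repeats = 1, seed = 7)
  for (seed in c(11, 12)) {
    mine <- loocv_mtpa(X, y, cfg, seed = seed)
    oracle <- oracle_loocv(X, y, cfg, seed = seed)
    expect_identical(mine$predictions, oracle)
  }
})

test_that("the held-out subject cannot leak into training", {
  toy <- make_separable_toy(n = 8, p = 5, signal_col = 2, gap = 2, seed = 9)
  cfg <- mtpa_config(n_repeats = 1, seed = 1)
  base <- loocv_mtpa(toy$X, toy$y, cfg, seed = 5)
  # canary column: constant in training rows, test label embedded in the
  # held-out row -- if any stage peeked at the held-out subject the
  # fold's prediction could change
  for (i in c(1, 4, 8)) {
    Xc <- cbind(toy$X, 0)
    Xc[i, ncol(Xc)] <- (2 * toy$y[i] - 1) * 10
    withc <- loocv_mtpa(Xc, toy$y, cfg, seed = 5)
    expect_identical(withc$predictions[i], base$predictions[i])
  }
})

test_that("repeated LOOCV is deterministic and collapses on separable data", {
  toy <- make_separable_toy(n = 8, p = 5, signal_col = 2, gap = 8)
  cfg <- mtpa_config(n_repeats = 5, seed = 2)
  res <- repeat_loocv(toy$X, toy$y, cfg, roi = "TPJ", measure = "toy")
  expect_equal(sd(res$per_repeat_accuracies), 0)
  expect_equal(res$accuracy, 1)
  expect_lte(res$mean_n_features, ncol(toy$X))
  expect_true(all(res$selection_frequency >= 0 &
                    res$selection_frequency <= 1))
  res2 <- repeat_loocv(toy$X, toy$y, cfg, roi = "TPJ", measure = "toy")
  expect_identical(res$selection_frequency, res2$selection_frequency)

  g <- glance(res)
  expect_equal(g$accuracy, 1)
  td <- tidy(res)
  expect_equal(nrow(td), ncol(toy$X))
})

test_that("shuffling subject order with per-subject seeds keeps the accuracy", {
  set.seed(24)
  n <- 12
  y <- rep(c(0L, 1L), each = 6)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- X[, 4] + 1.2 * y
  cfg <- mtpa_config(n_repeats = 1)
  seeds <- vapply(seq_len(n), function(i) derive_seed(99, i), integer(1))
  base <- loocv_mtpa(X, y, cfg, fold_seeds = seeds,
                     subject_ids = seq_len(n))
  perm <- sample(n)
  shuffled <- loocv_mtpa(X[perm, ], y[perm], cfg, fold_seeds = seeds[perm],
                         subject_ids = perm)
  expect_equal(shuffled$accuracy, base$accuracy)
  expect_identical(shuffled$predictions, base$predictions[perm])
})

test_that("the ridge baseline classifies separable data perfectly", {
  set.seed(1)
  n <- 16
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 5, sd = 0.3), n, 5)
  X[, 2] <- X[, 2] + 10 * y
  acc <- ridge_baseline(X, y, mtpa_config(n_repeats = 2, seed = 3))
  expect_equal(acc, 1)
})
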