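#' MTPA configuration
#'
#' Settings of the multitimepoint pattern analysis: an elastic-net
#' "temporal searchlight" (mixing parameter `alpha = 0.9`, close to
#' lasso, to encourage sparsity while tolerating multicollinearity among
#' neighbouring timepoints) selects informative timepoints, an
#' (essentially) unpenalized logistic refit on the selected timepoints
#' classifies, and the whole leave-one-out cycle is repeated
#' `n_repeats` times to average over the stochastic class balancing.
#'
#' @param alpha Elastic-net mixing parameter in (0, 1].
#' @param cv_folds Folds of the internal cross-validation that picks the
#'   regularization strength lambda (deviance criterion).
#' @param nlambda Length of the lambda path.
#' @param lambda Optional fixed lambda; when supplied the internal CV is
#'   skipped (used to scale large permutation simulations; applied
#'   identically to observed and permuted data).
#' @param n_repeats Number of LOOCV repetitions averaged.
#' @param ridge Stabilizing ridge added to the logistic refit.
#' @param zero_feature_fallback Strategy when no timepoint is selected;
#'   `"majority"` predicts the training majority class (ties resolved by
#'   a seeded coin flip).
#' @param seed Master seed; per-repeat seeds are `seed + repeat index`
#'   and per-fold seeds are `derive_seed(repeat seed, fold index)`.
#' @return A list of class `mtpa_config`.
#' @export
mtpa_config <- function(alpha = 0.9, cv_folds = 10, nlambda = 100,
                        lambda = NULL, n_repeats = 50, ridge = 1e-6,
                        zero_feature_fallback = "majority", seed = 1L) {
  if (alpha <= 0 || alpha > 1) nl_abort("`alpha` must lie in (0, 1].")
  if (n_repeats < 1) nl_abort("`n_repeats` must be at least 1.")
  structure(
    list(alpha = alpha, cv_folds = as.integer(cv_folds),
         nlambda = as.integer(nlambda), lambda = lambda,
         n_repeats = as.integer(n_repeats), ridge = ridge,
         zero_feature_fallback = zero_feature_fallback,
         seed = as.integer(seed)),
    class = "mtpa_config"
  )
}

# Internal: coerce labels to 0/1 integer
as_binary <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(factor(y)) - 1L
  } else {
    y <- as.integer(y)
  }
  if (!all(y %in% c(0L, 1L))) nl_abort("Labels must be binary.")
  y
}

# Internal: stratified fold assignment, deterministic given seed
stratified_folds <- function(y, nfolds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  foldid
}

# Internal: lambda path + deviance-minimizing lambda by stratified
# k-fold CV (total held-out binomial deviance). Returns the full-path
# fit and the chosen lambda.
glmnet_cv <- function(X, y, alpha, nlambda, cv_folds, seed) {
  path <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                   nlambda = nlambda)
  )
  lam <- path$lambda
  nf <- min(cv_folds, min(table(y)))
  if (nf < 2 || length(lam) < 2) {
    return(list(path = path, lambda_min = lam[length(lam)]))
  }
  foldid <- stratified_folds(y, nf, seed)
  dev <- numeric(length(lam))
  for (f in seq_len(nf)) {
    hold <- foldid == f
    fit <- suppressWarnings(
      glmnet::glmnet(X[!hold, , drop = FALSE], y[!hold],
                     family = "binomial", alpha = alpha, lambda = lam)
    )
    p <- stats::predict(fit, X[hold, , drop = FALSE], s = lam,
                        type = "response")
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    yk <- y[hold]
    dev <- dev - 2 * colSums(yk * log(p) + (1 - yk) * log(1 - p))
  }
  list(path = path, lambda_min = lam[which.min(dev)])
}

#' Elastic-net temporal feature selection
#'
#' Fits an elastic-net-penalized logistic path over all timepoints and
#' returns the indices of timepoints with nonzero coefficients at the
#' regularization strength chosen by internal stratified k-fold
#' cross-validation (held-out binomial deviance). May return an empty
#' set.
#'
#' @param X Samples-by-timepoints matrix.
#' @param y Binary labels (at least two cases per class).
#' @param cfg An [mtpa_config()].
#' @param seed Seed for the internal fold assignment.
#' @return Integer vector of selected timepoint indices (possibly empty).
#' @export
elastic_net_select <- function(X, y, cfg = mtpa_config(), seed = 1L) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) nl_abort("Labels are constant: nothing to select.")
  if (!all(is.finite(X))) nl_abort("`X` must be finite.")
  if (!is.null(cfg$lambda)) {
    lam_path <- sort(unique(c(cfg$lambda * 3, cfg$lambda)),
                     decreasing = TRUE)
    fit <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = cfg$alpha,
                     lambda = lam_path)
    )
    # the requested lambda is the last path entry; read the sparse
    # coefficient column directly
    beta <- fit$beta[, ncol(fit$beta)]
    return(as.integer(which(beta != 0)))
  }
  cv <- glmnet_cv(X, y, cfg$alpha, cfg$nlambda, cfg$cv_folds, seed)
  co <- stats::coef(cv$path, s = cv$lambda_min)
  which(as.numeric(co)[-1] != 0)
}

#' Logistic refit on the selected timepoints
#'
#' Separates selection from estimation: after the elastic net has chosen
#' timepoints, an (essentially) unpenalized logistic model is fit to the
#' full selected features by iteratively reweighted least squares with a
#' tiny stabilizing ridge, so perfect separation yields a usable
#' classifier instead of a failure. With zero selected features the
#' model falls back to an intercept-only majority-class predictor (ties
#' are resolved by a seeded coin flip at prediction time).
#'
#' @param X_selected Training matrix restricted to selected timepoints
#'   (zero columns allowed).
#' @param y Binary training labels.
#' @param ridge Stabilizing ridge on the non-intercept coefficients.
#' @return A list of class `selected_logistic`.
#' @export
fit_selected_logistic <- function(X_selected, y, ridge = 1e-6) {
  y <- as_binary(y)
  if (is.null(dim(X_selected))) X_selected <- cbind(X_selected)
  p <- ncol(X_selected)
  if (p == 0) {
    return(structure(
      list(type = "intercept", p1 = mean(y), coef = numeric(0),
           intercept = stats::qlogis(pmin(pmax(mean(y), 1e-10), 1 - 1e-10))),
      class = "selected_logistic"
    ))
  }
  Xa <- cbind(1, X_selected)
  pen <- diag(c(0, rep(ridge, p)), p + 1)
  beta <- numeric(p + 1)
  for (it in 1:25) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- tryCatch(
      solve(crossprod(Xa, Xa * w) + pen, crossprod(Xa, w * z)),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < 1e-8) break
    # separated fits saturate early: once every fitted probability is
    # pinned to 0/1 further Newton steps cannot change a prediction
    if (max(abs(drop(Xa %*% beta))) > 15) break
  }
  structure(
    list(type = "logistic", intercept = beta[1], coef = beta[-1]),
    class = "selected_logistic"
  )
}

#' @export
predict.selected_logistic <- function(object, newdata, tie_seed = 1L, ...) {
  if (object$type == "intercept") {
    p1 <- object$p1
    n <- if (is.null(dim(newdata))) 1L else nrow(newdata)
    if (p1 == 0.5) {
      return(with_seed(tie_seed, sample(c(0L, 1L), n, replace = TRUE)))
    }
    return(rep(as.integer(p1 > 0.5), n))
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  eta <- drop(object$intercept + newdata %*% object$coef)
  pr <- stats::plogis(eta)
  out <- as.integer(pr > 0.5)
  ties <- pr == 0.5
  if (any(ties)) {
    out[ties] <- with_seed(tie_seed,
                           sample(c(0L, 1L), sum(ties), replace = TRUE))
  }
  out
}

#' One repetition of leave-one-out MTPA
#'
#' For each fold: hold one subject out, upsample the minority class of
#' the remaining subjects, run elastic-net timepoint selection, refit a
#' logistic model on the selected timepoints, and predict the held-out
#' subject. The held-out subject never enters balancing, lambda
#' selection, feature selection, or the refit.
#'
#' @param X Subjects-by-timepoints matrix.
#' @param y Binary labels (length `nrow(X)`, at least 4 subjects).
#' @param cfg An [mtpa_config()].
#' @param seed Seed for this repetition; per-fold seeds are derived as
#'   `derive_seed(seed, fold)`.
#' @param fold_seeds Optional explicit per-fold (per-subject) seeds.
#' @param subject_ids Optional stable subject identifiers. Training rows
#'   are canonicalized to identifier order inside every fold, so results
#'   are invariant to the order subjects arrive in when per-subject
#'   seeds are supplied.
#' @return A list: `accuracy`, `correct` (0/1 per fold), `predictions`,
#'   `selection` (folds-by-timepoints logical matrix), `n_features`.
#' @export
loocv_mtpa <- function(X, y, cfg = mtpa_config(), seed = 1L,
                       fold_seeds = NULL, subject_ids = NULL) {
  y <- as_binary(y)
  n <- nrow(X)
  if (length(y) != n) nl_abort("`y` must have one label per row of `X`.")
  if (n < 4) nl_abort("LOOCV needs at least 4 subjects.")
  if (min(table(y)) < 2) nl_abort("Each class needs at least 2 subjects.")
  if (is.null(fold_seeds)) {
    fold_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i),
                         integer(1))
  }
  if (is.null(subject_ids)) subject_ids <- seq_len(n)
  sel_mat <- matrix(FALSE, n, ncol(X))
  pred <- integer(n)
  nfeat <- integer(n)
  for (i in seq_len(n)) {
    s_i <- fold_seeds[i]
    ord <- order(subject_ids[-i])
    Xtr <- X[-i, , drop = FALSE][ord, , drop = FALSE]
    ytr <- y[-i][ord]
    bal <- upsample_minority(ytr, seed = s_i)
    Xb <- Xtr[bal, , drop = FALSE]
    yb <- ytr[bal]
    sel <- elastic_net_select(Xb, yb, cfg, seed = derive_seed(s_i, 1L))
    fit <- fit_selected_logistic(Xb[, sel, drop = FALSE], yb, cfg$ridge)
    pred[i] <- predict(fit, X[i, sel, drop = FALSE],
                       tie_seed = derive_seed(s_i, 2L))
    sel_mat[i, sel] <- TRUE
    nfeat[i] <- length(sel)
  }
  correct <- as.integer(pred == y)
  list(accuracy = mean(correct), correct = correct, predictions = pred,
       selection = sel_mat, n_features = nfeat)
}

#' Repeated leave-one-out MTPA
#'
#' Runs [loocv_mtpa()] `n_repeats` times with per-repeat seeds
#' `cfg$seed + repeat` (the class upsampling redraws every fold of every
#' repeat) and averages: overall accuracy, per-timepoint selection
#' frequency (share of fold-by-repeat runs in which the timepoint was
#' selected), and mean retained-feature count.
#'
#' @param X Subjects-by-timepoints matrix.
#' @param y Binary labels.
#' @param cfg An [mtpa_config()].
#' @param roi,measure Optional metadata carried into the result.
#' @return A list of class `mtpa_result`.
#' @export
repeat_loocv <- function(X, y, cfg = mtpa_config(), roi = NA_character_,
                         measure = NA_character_) {
  y <- as_binary(y)
  runs <- purrr::map(seq_len(cfg$n_repeats), function(r) {
    loocv_mtpa(X, y, cfg, seed = cfg$seed + r)
  })
  sel_freq <- Reduce(`+`, purrr::map(runs, ~ colSums(.x$selection))) /
    (cfg$n_repeats * nrow(X))
  structure(
    list(
      roi = roi, measure = measure,
      accuracy = mean(purrr::map_dbl(runs, "accuracy")),
      per_repeat_accuracies = purrr::map_dbl(runs, "accuracy"),
      selection_frequency = sel_freq,
      mean_n_features = mean(purrr::map_dbl(runs, ~ mean(.x$n_features))),
      n_participants = nrow(X), n_timepoints = ncol(X),
      n_repeats = cfg$n_repeats
    ),
    class = "mtpa_result"
  )
}

#' @export
print.mtpa_result <- function(x, ...) {
  cat(sprintf(
    "MTPA result%s: accuracy %.2f%% (%d repeats), %.2f features retained\n",
    if (is.na(x$roi)) "" else sprintf(" [%s / %s]", x$roi, x$measure),
    100 * x$accuracy, x$n_repeats, x$mean_n_features
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mtpa_result <- function(x, ...) {
  tibble::tibble(
    roi = x$roi, measure = x$measure,
    time_s = seq_len(x$n_timepoints) - 1,
    selection_frequency = x$selection_frequency
  )
}

#' @export
glance.mtpa_result <- function(x, ...) {
  tibble::tibble(
    roi = x$roi, measure = x$measure, accuracy = x$accuracy,
    accuracy_sd = stats::sd(x$per_repeat_accuracies),
    mean_n_features = x$mean_n_features,
    n_participants = x$n_participants,
    n_timepoints = x$n_timepoints, n_repeats = x$n_repeats
  )
}

#' Ridge baseline without feature selection
#'
#' Ablation comparator: the same repeated-LOOCV protocol (including
#' within-fold minority upsampling and internal lambda selection) but a
#' ridge-penalized logistic model on all timepoints, with no temporal
#' feature selection and no refit.
#'
#' @param X Subjects-by-timepoints matrix.
#' @param y Binary labels.
#' @param cfg An [mtpa_config()] (its `alpha` is ignored; ridge uses 0).
#' @return Averaged LOOCV accuracy over `cfg$n_repeats` repeats.
#' @export
ridge_baseline <- function(X, y, cfg = mtpa_config()) {
  y <- as_binary(y)
  n <- nrow(X)
  if (n < 4) nl_abort("LOOCV needs at least 4 subjects.")
  accs <- vapply(seq_len(cfg$n_repeats), function(r) {
    seed_r <- cfg$seed + r
    pred <- integer(n)
    for (i in seq_len(n)) {
      s_i <- derive_seed(seed_r, i)
      Xtr <- X[-i, , drop = FALSE]
      ytr <- y[-i]
      bal <- upsample_minority(ytr, seed = s_i)
      Xb <- Xtr[bal, , drop = FALSE]
      yb <- ytr[bal]
      cv <- glmnet_cv(Xb, yb, alpha = 0, nlambda = cfg$nlambda,
                      cv_folds = cfg$cv_folds, seed = derive_seed(s_i, 1L))
      pr <- stats::predict(cv$path, X[i, , drop = FALSE], s = cv$lambda_min,
                           type = "response")
      pred[i] <- if (pr[1] == 0.5) {
        with_seed(derive_seed(s_i, 2L), sample(c(0L, 1L), 1))
      } else {
        as.integer(pr[1] > 0.5)
      }
    }
    mean(pred == y)
  }, numeric(1))
  mean(accs)
}
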