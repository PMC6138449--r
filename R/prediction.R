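# Trait prediction from connectomes: train-only deconfounding, leave-one-
# family-out cross-validation, edge filtering, the univariate positive /
# negative network-strength models, and the filtered elastic-net model with
# nested quartile-stratified alpha selection.

FULL_CONFOUNDS <- c("gender", "age", "handedness", "gF", "brain_size",
                    "motion_rest1", "motion_rest2", "recon_version")
MINIMAL_CONFOUNDS <- c("recon_version", "motion_rest1", "motion_rest2",
                       "brain_size")

#' Prediction model configuration
#'
#' @param model `"univariate_pos"`, `"univariate_neg"` or `"elastic_net"`.
#' @param filter_p two-sided p-value threshold of the edge filter.
#' @param l1_ratio elastic-net L1 mixing weight (0.01: almost pure ridge).
#' @param n_alphas number of penalty values on the geometric grid.
#' @param inner_folds inner cross-validation folds for penalty selection.
#' @param deconfound_set `"full"`, `"minimal"` or `"none"`.
#' @param target name of the predicted score; when the target is itself in
#'   the confound list (fluid intelligence), it is excluded from its own
#'   deconfounding set.
#' @export
model_config <- function(model = c("univariate_pos", "univariate_neg",
                                   "elastic_net"),
                         filter_p = 0.01, l1_ratio = 0.01, n_alphas = 50,
                         inner_folds = 3,
                         deconfound_set = c("full", "minimal", "none"),
                         target = NULL) {
  model <- match.arg(model)
  deconfound_set <- match.arg(deconfound_set)
  .assert(filter_p > 0 && filter_p < 1, "filter_p must lie in (0, 1)")
  .assert(l1_ratio >= 0 && l1_ratio <= 1, "l1_ratio must lie in [0, 1]")
  structure(list(model = model, filter_p = filter_p, l1_ratio = l1_ratio,
                 n_alphas = n_alphas, inner_folds = inner_folds,
                 deconfound_set = deconfound_set, target = target),
            class = "model_config")
}

#' Select confound columns for a deconfounding set
#'
#' @param confounds data frame of available confound columns.
#' @param set `"full"`, `"minimal"` or `"none"`.
#' @param target name of the predicted score; removed from its own set.
#' @export
confound_set <- function(confounds, set = c("full", "minimal", "none"),
                         target = NULL) {
  set <- match.arg(set)
  if (set == "none") return(character(0))
  want <- if (set == "full") FULL_CONFOUNDS else MINIMAL_CONFOUNDS
  want <- intersect(want, names(confounds))
  setdiff(want, target)
}

#' Fit a deconfounding model on training subjects only
#'
#' Multiple linear regression of the score on the confounds, fitted on the
#' training subjects; the stored coefficients are later applied unchanged to
#' both training and held-out subjects ([apply_deconfound()]), so no
#' information flows from test to train.
#'
#' @param y score vector (all subjects).
#' @param confounds data frame/matrix of confound columns (all subjects).
#' @param train_idx indices of the training subjects.
#' @param columns confound column names to use (default: all columns).
#' @return a `deconfound_model`.
#' @export
fit_deconfound <- function(y, confounds, train_idx,
                           columns = colnames(confounds)) {
  X <- as.matrix(as.data.frame(confounds)[, columns, drop = FALSE])
  .assert(!anyNA(X) && !anyNA(y), "missing values in scores or confounds")
  .assert(length(train_idx) >= ncol(X) + 2,
          "need at least %d training subjects for %d confounds",
          ncol(X) + 2, ncol(X))
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xd[train_idx, , drop = FALSE], y[train_idx])
  beta <- fit$coefficients
  if (anyNA(beta)) {
    .warnf("collinear confound(s) dropped: %s",
           paste(names(beta)[is.na(beta)], collapse = ", "))
    beta[is.na(beta)] <- 0
  }
  structure(list(columns = columns, beta = beta, fitted_on = train_idx),
            class = "deconfound_model")
}

#' Apply a fitted deconfounding model
#'
#' @param model a `deconfound_model` from [fit_deconfound()].
#' @param y score vector (all subjects).
#' @param confounds confound table (all subjects).
#' @param idx subjects to residualize.
#' @return residual scores for `idx`.
#' @export
apply_deconfound <- function(model, y, confounds, idx = seq_along(y)) {
  X <- as.matrix(as.data.frame(confounds)[, model$columns, drop = FALSE])
  Xd <- cbind(`(Intercept)` = 1, X)[idx, , drop = FALSE]
  as.numeric(y[idx] - Xd %*% model$beta)
}

#' Leave-one-family-out cross-validation folds
#'
#' One fold per unique family: the fold's test set is the whole family, the
#' training set is everyone else. Folds are ordered by family id and
#' partition the cohort.
#'
#' @param family_ids family identifier per subject.
#' @return list of `list(train, test)` index vectors.
#' @export
lofo_splits <- function(family_ids) {
  .assert(!anyNA(family_ids), "missing family id(s)")
  fams <- sort(unique(as.character(family_ids)))
  all_idx <- seq_along(family_ids)
  lapply(fams, function(f) {
    test <- which(as.character(family_ids) == f)
    list(train = setdiff(all_idx, test), test = test)
  })
}

#' Filter edges by correlation with the training score
#'
#' Per-edge Pearson correlation with the training score; two-sided p-values
#' from the t transform `t = r * sqrt((n-2)/(1-r^2))`. Edges with `p <
#' filter_p` are kept, split by correlation sign. Zero-variance edges are
#' excluded with a warning.
#'
#' @param X_train training edge matrix (subjects x edges).
#' @param y_train training scores.
#' @param filter_p p-value threshold.
#' @return list with logical `pos_mask`, `neg_mask`, and the edge
#'   correlations `r`.
#' @export
filter_edges <- function(X_train, y_train, filter_p = 0.01) {
  n <- nrow(X_train)
  .assert(n > 3, "need more than 3 training subjects")
  .assert(stats::var(y_train) > 0, "training score is constant")
  r <- suppressWarnings(as.vector(stats::cor(unclass(X_train), y_train)))
  if (anyNA(r)) {
    .warnf("%d zero-variance edge(s) excluded from filtering", sum(is.na(r)))
  }
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  ok <- !is.na(r)
  list(pos_mask = ok & p < filter_p & r > 0,
       neg_mask = ok & p < filter_p & r < 0,
       r = r)
}

#' Univariate network-strength model
#'
#' The single predictor is the network strength: the sum of the masked
#' edges' Fisher-z values. A line is fitted to the training strengths and
#' evaluated at the test strengths. With an empty mask (or zero strength
#' variance) the prediction falls back to the training mean.
#'
#' @param X_train,y_train training data.
#' @param X_test test edge matrix.
#' @param mask logical edge mask from [filter_edges()].
#' @return list with `predictions`, `n_edges` used, and `fallback` flag.
#' @export
cpm_univariate <- function(X_train, y_train, X_test, mask) {
  if (sum(mask) == 0) {
    return(list(predictions = rep(mean(y_train), nrow(X_test)),
                n_edges = 0L, fallback = TRUE))
  }
  s_train <- rowSums(unclass(X_train)[, mask, drop = FALSE])
  s_test <- rowSums(unclass(X_test)[, mask, drop = FALSE])
  if (stats::var(s_train) == 0) {
    return(list(predictions = rep(mean(y_train), nrow(X_test)),
                n_edges = sum(mask), fallback = TRUE))
  }
  b <- stats::cov(s_train, y_train) / stats::var(s_train)
  a <- mean(y_train) - b * mean(s_train)
  list(predictions = unname(a + b * s_test), n_edges = sum(mask),
       fallback = FALSE)
}

# deterministic quartile-stratified inner folds: 4 equal-count bins of
# y_train used as strata, round-robin within bin by score rank
.stratified_folds <- function(y, k) {
  n <- length(y)
  if (n < 2 * k) {
    k <- max(2L, n %/% 2L)
    .warnf("inner folds reduced to %d (training fold too small)", k)
  }
  qs <- stats::quantile(y, probs = c(0.25, 0.5, 0.75), type = 7)
  bin <- findInterval(y, unique(qs))
  fold <- integer(n)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    fold[idx[order(y[idx])]] <- (seq_along(idx) - 1L) %% k + 1L
  }
  list(fold = fold, k = k)
}

#' Filtered elastic-net model with nested penalty selection
#'
#' Features (the union of the positively and negatively filtered edges) are
#' standardized by training mean/SD. The penalty grid is `n_alphas`
#' geometrically spaced values spanning `[1e-4, 1] * alpha_max`, where
#' `alpha_max` is the smallest penalty that zeroes all coefficients at the
#' given L1 ratio. The penalty is chosen to minimize the mean inner-fold
#' squared error over a quartile-stratified inner split (ties go to the
#' larger penalty), then the model is refitted on the full training fold.
#'
#' @param X_train,y_train training data.
#' @param X_test test edge matrix.
#' @param mask logical edge mask (union of positive and negative sets).
#' @param config a [model_config()].
#' @return list with `predictions`, `chosen_alpha`, `n_edges`, `fallback`.
#' @export
elasticnet_model <- function(X_train, y_train, X_test, mask,
                             config = model_config("elastic_net")) {
  if (sum(mask) == 0) {
    return(list(predictions = rep(mean(y_train), nrow(X_test)),
                chosen_alpha = NA_real_, n_edges = 0L, fallback = TRUE))
  }
  Xtr <- unclass(X_train)[, mask, drop = FALSE]
  Xte <- unclass(X_test)[, mask, drop = FALSE]
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {
    return(list(predictions = rep(mean(y_train), nrow(X_test)),
                chosen_alpha = NA_real_, n_edges = 0L, fallback = TRUE))
  }
  Xtr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  Xte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  n <- nrow(Xtr)
  l1 <- max(config$l1_ratio, 1e-3)   # alpha_max is infinite at pure ridge
  alpha_max <- max(abs(crossprod(Xtr, y_train - mean(y_train)))) / (n * l1)
  grid <- alpha_max * exp(seq(log(1), log(1e-4), length.out = config$n_alphas))

  if (ncol(Xtr) == 1) {   # glmnet requires >= 2 columns; duplicate and halve
    fit_glmnet <- function(x, y) {
      glmnet::glmnet(cbind(x, x), y, alpha = config$l1_ratio, lambda = grid,
                     standardize = FALSE, thresh = 1e-10)
    }
    predict_glmnet <- function(fit, x, s) {
      as.numeric(glmnet::predict.glmnet(fit, cbind(x, x), s = s, exact = FALSE))
    }
  } else {
    fit_glmnet <- function(x, y) {
      glmnet::glmnet(x, y, alpha = config$l1_ratio, lambda = grid,
                     standardize = FALSE, thresh = 1e-10)
    }
    predict_glmnet <- function(fit, x, s) {
      as.numeric(glmnet::predict.glmnet(fit, x, s = s, exact = FALSE))
    }
  }

  folds <- .stratified_folds(y_train, config$inner_folds)
  mse <- matrix(NA_real_, folds$k, length(grid))
  for (f in seq_len(folds$k)) {
    inner_tr <- folds$fold != f
    fit <- fit_glmnet(Xtr[inner_tr, , drop = FALSE], y_train[inner_tr])
    pred <- glmnet::predict.glmnet(
      fit,
      if (ncol(Xtr) == 1) cbind(Xtr[!inner_tr, , drop = FALSE],
                                Xtr[!inner_tr, , drop = FALSE])
      else Xtr[!inner_tr, , drop = FALSE],
      s = grid, exact = FALSE)
    mse[f, ] <- colMeans((pred - y_train[!inner_tr])^2)
  }
  mean_mse <- colMeans(mse)
  chosen <- grid[which.min(mean_mse)]  # grid is decreasing: ties -> larger alpha
  final <- fit_glmnet(Xtr, y_train)
  list(predictions = predict_glmnet(final, Xte, chosen),
       chosen_alpha = chosen, n_edges = ncol(Xtr), fallback = FALSE,
       grid = grid, coefficients = as.matrix(final$beta),
       intercepts = final$a0)
}

#' Leave-one-family-out cross-validated prediction
#'
#' For each family-based fold: fit the deconfounding regression on the
#' training subjects, residualize training and test scores with the stored
#' coefficients, filter edges on the training fold, fit the configured model
#' on the training fold, and predict the held-out family. Every subject is
#' predicted exactly once; the recorded observed scores are the fold-specific
#' deconfounded test values.
#'
#' @param X `edge_matrix` of Fisher-z edge values (subjects x edges).
#' @param y raw scores.
#' @param confounds data frame of confound columns (may be `NULL` when
#'   `config$deconfound_set == "none"`).
#' @param family_ids family identifier per subject.
#' @param config a [model_config()].
#' @return a `prediction_result`: list with `observed`, `predicted`, `fold`
#'   (per subject), `fold_info` (per-fold edge counts / chosen penalty), and
#'   the `config`.
#' @export
predict_cv <- function(X, y, confounds, family_ids,
                       config = model_config()) {
  .assert(inherits(config, "model_config"), "config must come from model_config()")
  Xu <- unclass(X)
  n <- nrow(Xu)
  .assert(length(y) == n && length(family_ids) == n,
          "X, y and family_ids disagree on the number of subjects")
  cols <- if (config$deconfound_set == "none") character(0) else
    confound_set(confounds, config$deconfound_set, config$target)
  deconfound <- length(cols) > 0
  Xd <- if (deconfound) {
    cbind(`(Intercept)` = 1,
          as.matrix(as.data.frame(confounds)[, cols, drop = FALSE]))
  } else {
    matrix(1, n, 1)
  }
  .assert(!anyNA(Xd) && !anyNA(y), "missing values in scores or confounds")
  splits <- lofo_splits(family_ids)

  # sufficient statistics so each fold's edgewise train correlations are a
  # rank-|family| downdate instead of a full recomputation (identical, up to
  # rounding, to filter_edges() on the training fold; asserted in tests)
  SX <- colSums(Xu)
  SXX <- colSums(Xu^2)
  XtXd <- crossprod(Xu, Xd)
  Xty <- as.numeric(crossprod(Xu, y))

  observed <- predicted <- rep(NA_real_, n)
  fold_id <- rep(NA_integer_, n)
  fold_info <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    tr <- splits[[k]]$train
    te <- splits[[k]]$test
    n_tr <- length(tr)
    Xte <- Xu[te, , drop = FALSE]
    if (deconfound) {
      .assert(n_tr >= ncol(Xd) + 1,
              "need at least %d training subjects for %d confounds",
              ncol(Xd) + 1, ncol(Xd) - 1)
      beta <- qr.coef(qr(Xd[tr, , drop = FALSE]), y[tr])
      beta[is.na(beta)] <- 0            # collinear confounds contribute nothing
      y_res <- y - as.numeric(Xd %*% beta)
      sxy_deconf <- as.numeric((XtXd - crossprod(Xte, Xd[te, , drop = FALSE])) %*% beta)
    } else {
      y_res <- y
      sxy_deconf <- 0
    }
    y_tr <- y_res[tr]
    y_te <- y_res[te]
    .assert(stats::var(y_tr) > 0, "training score is constant")

    mean_x <- (SX - colSums(Xte)) / n_tr
    ssx <- pmax(SXX - colSums(Xte^2) - n_tr * mean_x^2, 0)
    sxy <- (Xty - as.numeric(crossprod(Xte, y[te]))) - sxy_deconf -
      n_tr * mean_x * mean(y_tr)
    ssy <- sum((y_tr - mean(y_tr))^2)
    r <- sxy / sqrt(ssx * ssy)
    tc <- stats::qt(1 - config$filter_p / 2, df = n_tr - 2)
    r_crit <- tc / sqrt(n_tr - 2 + tc^2)
    pos_mask <- is.finite(r) & r > r_crit
    neg_mask <- is.finite(r) & r < -r_crit

    fit <- switch(config$model,
      univariate_pos = .cpm_fast(Xu, tr, te, y_tr, pos_mask),
      univariate_neg = .cpm_fast(Xu, tr, te, y_tr, neg_mask),
      elastic_net = {
        mask <- pos_mask | neg_mask
        Xm <- Xu[, mask, drop = FALSE]
        elasticnet_model(Xm[tr, , drop = FALSE], y_tr,
                         Xm[te, , drop = FALSE],
                         rep(TRUE, ncol(Xm)), config)
      })
    observed[te] <- y_te
    predicted[te] <- fit$predictions
    fold_id[te] <- k
    fold_info[[k]] <- list(n_pos = sum(pos_mask),
                           n_neg = sum(neg_mask),
                           n_edges_used = fit$n_edges,
                           chosen_alpha = fit$chosen_alpha %||% NA_real_,
                           fallback = fit$fallback)
  }
  structure(list(observed = observed, predicted = predicted, fold = fold_id,
                 fold_info = fold_info, config = config),
            class = "prediction_result")
}

# univariate network-strength fit touching only the masked columns
.cpm_fast <- function(Xu, tr, te, y_tr, mask) {
  if (sum(mask) == 0) {
    return(list(predictions = rep(mean(y_tr), length(te)),
                n_edges = 0L, fallback = TRUE))
  }
  s_all <- rowSums(Xu[, mask, drop = FALSE])
  s_tr <- s_all[tr]
  if (stats::var(s_tr) == 0) {
    return(list(predictions = rep(mean(y_tr), length(te)),
                n_edges = sum(mask), fallback = TRUE))
  }
  b <- stats::cov(s_tr, y_tr) / stats::var(s_tr)
  a <- mean(y_tr) - b * mean(s_tr)
  list(predictions = unname(a + b * s_all[te]), n_edges = sum(mask),
       fallback = FALSE)
}

#' Ordinary leave-one-out variant (for family-bias comparisons)
#'
#' Identical chain to [predict_cv()] but with one fold per subject,
#' ignoring family structure. Provided to demonstrate the optimism that
#' kinship leakage induces relative to leave-one-family-out folds.
#'
#' @inheritParams predict_cv
#' @export
predict_cv_loo <- function(X, y, confounds, config = model_config()) {
  predict_cv(X, y, confounds, family_ids = seq_len(nrow(X)), config = config)
}
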