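# Prediction-quality metrics for cross-validated predictions (Pearson r,
# cross-validated R^2, RMSD, nRMSD) and the family-preserving permutation
# test for their significance.

#' Evaluate observed vs cross-validated predicted scores
#'
#' Computes the Pearson correlation `r`, the cross-validated coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` (which can be negative: in
#' cross-validation the model can do worse than predicting the mean), the
#' root-mean-square deviation RMSD, and the normalized RMSD
#' (RMSD / SD of the observed scores). Squaring `r` is *not* a valid estimate
#' of explained variance in this setting; use `r2`.
#'
#' Two denominator conventions are offered. `"population"` (default) uses
#' 1/n for RMSD and the population SD of `obs`, so that
#' `nrmsd^2 + r2 == 1` exactly. `"residual"` uses the residual degrees of
#' freedom (n-2, as for the SD of residuals about a fitted line) for RMSD and
#' the n-1 sample SD, so `nrmsd = sqrt((1 - r2) * (n-1)/(n-2))`.
#'
#' @param obs observed scores.
#' @param pred predicted scores (same length).
#' @param convention `"population"` or `"residual"` (see Details).
#' @return list with `r`, `r2`, `rmsd`, `nrmsd`, `n`, and
#'   `constant_prediction` flag (`r` is reported as 0 when the predictions
#'   are constant).
#' @export
evaluate_predictions <- function(obs, pred,
                                 convention = c("population", "residual")) {
  convention <- match.arg(convention)
  .assert(length(obs) == length(pred), "obs and pred differ in length")
  .assert(all(is.finite(obs)) && all(is.finite(pred)),
          "obs/pred contain non-finite values")
  n <- length(obs)
  .assert(n >= 3, "need at least 3 observations")
  .assert(stats::var(obs) > 0, "observed scores are constant")

  constant_pred <- stats::var(pred) == 0
  r <- if (constant_pred) 0 else stats::cor(obs, pred)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot
  if (convention == "population") {
    rmsd <- sqrt(ss_res / n)
    nrmsd <- rmsd / .pop_sd(obs)
  } else {
    rmsd <- sqrt(ss_res / (n - 2))
    nrmsd <- rmsd / stats::sd(obs)
  }
  list(r = r, r2 = r2, rmsd = rmsd, nrmsd = nrmsd, n = n,
       constant_prediction = constant_pred)
}

#' Normalized RMSD implied by a cross-validated R-squared
#'
#' Under the population-SD convention (`n = Inf`) this is exactly
#' `sqrt(1 - r2)`. With a finite `n`, the RMSD denominator is the residual
#' degrees of freedom n-2 (the SD of residuals) while the observed-score SD
#' uses n-1, giving `sqrt((1 - r2) * (n - 1) / (n - 2))`; this is the
#' convention under which published (r, R^2, nRMSD) triplets at large n are
#' internally consistent.
#'
#' @param r2 cross-validated coefficient of determination (may be negative).
#' @param n number of observations; `Inf` for the population convention.
#' @export
nrmsd_from_r2 <- function(r2, n = Inf) {
  .assert(all(r2 <= 1), "r2 must be <= 1")
  if (is.infinite(n)) return(sqrt(1 - r2))
  .assert(n > 2, "n must exceed 2")
  sqrt((1 - r2) * (n - 1) / (n - 2))
}

#' Family-preserving permutation test for cross-validated prediction
#'
#' Re-runs the entire deconfound + leave-one-family-out prediction chain
#' after randomly shuffling the raw scores between subjects, keeping
#' everything else (confounds, edges, family-based folds) exactly the same,
#' and compares the observed metric to the permutation replicates with the
#' one-tailed empirical rule `p = (1 + #{replicate >= observed}) / (n_perm + 1)`.
#'
#' @param X `edge_matrix` of Fisher-z edge values (subjects x edges).
#' @param y raw (not deconfounded) scores.
#' @param confounds data frame of confound columns.
#' @param family_ids family identifier per subject.
#' @param config [model_config()].
#' @param n_perm number of permutations (the reference analysis used 1000).
#' @param seed integer seed for the permutation stream.
#' @param metric `"r"` (default) or `"r2"`.
#' @return list with `observed`, `replicates`, `p`, `n_perm`, `n_failed`,
#'   `metric`, `seed`.
#' @export
permutation_test <- function(X, y, confounds, family_ids, config,
                             n_perm = 1000, seed = 1, metric = c("r", "r2")) {
  metric <- match.arg(metric)
  .assert(n_perm >= 1, "n_perm must be >= 1")
  run_once <- function(scores) {
    res <- predict_cv(X, scores, confounds, family_ids, config)
    evaluate_predictions(res$observed, res$predicted)[[metric]]
  }
  observed <- run_once(y)
  set.seed(seed)
  replicates <- rep(NA_real_, n_perm)
  n_failed <- 0L
  for (b in seq_len(n_perm)) {
    yb <- y[sample.int(length(y))]
    replicates[b] <- tryCatch(run_once(yb), error = function(e) {
      n_failed <<- n_failed + 1L
      NA_real_
    })
  }
  ok <- replicates[!is.na(replicates)]
  p <- (1 + sum(ok >= observed)) / (length(ok) + 1)
  list(observed = observed, replicates = replicates, p = p,
       n_perm = n_perm, n_failed = n_failed, metric = metric, seed = seed)
}
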