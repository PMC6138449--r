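# deconfounding, LOFO folds, edge filtering, CPM models, elastic net

test_that("deconfounding fits on training subjects only", {
  set.seed(1)
  n <- 60
  conf <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * conf$a + rnorm(n, sd = 0.1)
  tr <- 1:40

  dm <- fit_deconfound(y, conf, tr)
  expect_lt(var(apply_deconfound(dm, y, conf, tr)), 0.02)

  # confound orthogonal to y: residual is just the demeaned training view
  y2 <- rnorm(n)
  orth <- data.frame(z = qr.resid(qr(cbind(1, y2)), rnorm(n)))
  dm2 <- fit_deconfound(y2, orth, tr)
  res2 <- apply_deconfound(dm2, y2, orth, tr)
  expect_equal(res2, y2[tr] - mean(y2[tr]) -
                 dm2$beta["z"] * (orth$z[tr] - mean(orth$z[tr])),
               tolerance = 1e-12)

  # leakage: perturbing test-subject scores leaves the coefficients untouched
  y3 <- y
  y3[41:60] <- y3[41:60] + 100
  dm3 <- fit_deconfound(y3, conf, tr)
  expect_identical(dm$beta, dm3$beta)

  # collinear confounds are dropped with a warning
  conf$c <- conf$a
  expect_warning(fit_deconfound(y, conf, tr), "collinear")
  conf$c <- NA
  expect_error(fit_deconfound(y, conf, tr), "missing")
})

test_that("confound sets follow the full/minimal definitions", {
  sim <- generate_cohort(null_signal_spec(10, n_parcels = 5, seed = 2))
  full <- confound_set(sim$cohort, "full")
  expect_setequal(full, c("gender", "age", "handedness", "gF", "brain_size",
                          "motion_rest1", "motion_rest2", "recon_version"))
  expect_setequal(confound_set(sim$cohort, "minimal"),
                  c("recon_version", "motion_rest1", "motion_rest2",
                    "brain_size"))
  # a score is never deconfounded against itself
  expect_false("gF" %in% confound_set(sim$cohort, "full", target = "gF"))
  expect_equal(confound_set(sim$cohort, "none"), character(0))
})

test_that("LOFO folds partition the cohort, one family per fold", {
  fam <- c("A", "A", "B", "C", "C")
  sp <- lofo_splits(fam)
  expect_length(sp, 3)
  expect_equal(lapply(sp, `[[`, "test"), list(c(1L, 2L), 3L, c(4L, 5L)))
  tests <- unlist(lapply(sp, `[[`, "test"))
  expect_setequal(tests, 1:5)
  expect_equal(anyDuplicated(tests), 0L)
  for (s in sp) expect_setequal(c(s$train, s$test), 1:5)

  # all singleton families: equals leave-one-out
  expect_length(lofo_splits(as.character(1:7)), 7)
  expect_error(lofo_splits(c("A", NA)), "missing")
})

test_that("edge filter keeps p < .01 edges split by sign", {
  set.seed(3)
  n <- 100
  y <- rnorm(n)
  X <- matrix(rnorm(n * 500), n)
  X[, 1] <- 0.9 * scale(y) + sqrt(1 - 0.81) * rnorm(n)   # planted r ~ .9
  X[, 2] <- -0.9 * scale(y) + sqrt(1 - 0.81) * rnorm(n)
  m <- filter_edges(X, y)
  expect_true(m$pos_mask[1])
  expect_true(m$neg_mask[2])
  expect_false(any(m$pos_mask & m$neg_mask))

  X[, 3] <- 7                                   # zero-variance edge excluded
  expect_warning(m2 <- filter_edges(X, y), "zero-variance")
  expect_false(m2$pos_mask[3] || m2$neg_mask[3])
  expect_error(filter_edges(X, rep(1, n)), "constant")
})

test_that("univariate model reduces to a line in network strength", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 30), n)
  mask <- rep(FALSE, 30)
  mask[1:5] <- TRUE
  strength <- rowSums(X[, 1:5])
  y <- strength                                  # y is exactly the strength
  fit <- cpm_univariate(X[1:40, ], y[1:40], X[41:50, ], mask)
  expect_equal(fit$predictions, strength[41:50], tolerance = 1e-10)

  # empty mask: fallback to the training mean
  fit2 <- cpm_univariate(X[1:40, ], y[1:40], X[41:50, ], rep(FALSE, 30))
  expect_true(fit2$fallback)
  expect_equal(fit2$predictions, rep(mean(y[1:40]), 10))

  # positive rescaling of all edges only rescales the slope
  fit3 <- cpm_univariate(3 * X[1:40, ], y[1:40], 3 * X[41:50, ], mask)
  expect_equal(fit3$predictions, fit$predictions, tolerance = 1e-10)
})

test_that("elastic net: OLS limit, grouping of duplicates, path monotonicity", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.3)
  X <- cbind(x, matrix(rnorm(n * 2, sd = 1e-8), n))  # one informative feature
  cfg <- model_config("elastic_net")
  fit <- elasticnet_model(X[1:90, 1, drop = FALSE], y[1:90],
                          X[91:120, 1, drop = FALSE], TRUE, cfg)
  ols <- lm(y[1:90] ~ scale(X[1:90, 1]))
  xs <- (X[91:120, 1] - mean(X[1:90, 1])) / sd(X[1:90, 1])
  expect_gt(cor(fit$predictions, coef(ols)[1] + coef(ols)[2] * xs), 0.999)

  # duplicated feature: near-ridge penalty splits the coefficient evenly
  # (checked at a mid-grid penalty where the ridge term is well conditioned)
  Xd <- cbind(x, x, rnorm(n))
  fitd <- elasticnet_model(Xd[1:90, ], y[1:90], Xd[91:120, ],
                           rep(TRUE, 3), cfg)
  mid <- 15
  expect_lt(abs(fitd$coefficients[1, mid] - fitd$coefficients[2, mid]), 1e-6)

  # coefficient norm non-increasing in the penalty across the grid
  norms <- sqrt(colSums(fitd$coefficients^2))   # grid is decreasing in alpha
  expect_true(all(diff(rev(norms)) <= 1e-6))

  # empty mask falls back to the training mean
  fe <- elasticnet_model(Xd[1:90, ], y[1:90], Xd[91:120, ],
                         rep(FALSE, 3), cfg)
  expect_true(fe$fallback)
})

test_that("predict_cv equals the composed exported operations fold by fold", {
  sim <- generate_cohort(planted_spec(60, effect = 0.4, n_signal_edges = 40,
                                      n_parcels = 30, seed = 6))
  X <- generate_session_edges(sim$truth, "REST1")
  y <- sim$cohort$gF
  cfg <- model_config("univariate_pos", deconfound_set = "full", target = "gF")
  res <- predict_cv(X, y, sim$cohort, sim$cohort$family_id, cfg)
  expect_true(all(!is.na(res$predicted)))
  expect_equal(sort(unique(res$fold)), seq_along(res$fold_info))

  splits <- lofo_splits(sim$cohort$family_id)
  cols <- confound_set(sim$cohort, "full", "gF")
  for (k in c(2, 7)) {
    tr <- splits[[k]]$train
    te <- splits[[k]]$test
    dm <- fit_deconfound(y, sim$cohort, tr, cols)
    y_tr <- apply_deconfound(dm, y, sim$cohort, tr)
    y_te <- apply_deconfound(dm, y, sim$cohort, te)
    m <- filter_edges(X[tr, , drop = FALSE], y_tr, 0.01)
    fit <- cpm_univariate(X[tr, , drop = FALSE], y_tr, X[te, , drop = FALSE],
                          m$pos_mask)
    expect_equal(res$observed[te], y_te, tolerance = 1e-10)
    expect_equal(res$predicted[te], fit$predictions, tolerance = 1e-8)
    expect_equal(res$fold_info[[k]]$n_pos, sum(m$pos_mask))
    expect_equal(res$fold_info[[k]]$n_neg, sum(m$neg_mask))
  }
})

test_that("fold components never see test data", {
  sim <- generate_cohort(planted_spec(50, effect = 0.4, n_signal_edges = 30,
                                      n_parcels = 30, seed = 7))
  X <- unclass(generate_session_edges(sim$truth, "REST1"))
  y <- sim$cohort$trait_O
  fam <- sim$cohort$family_id
  te <- which(fam == fam[1])

  for (model in c("univariate_pos", "elastic_net")) {
    cfg <- model_config(model, deconfound_set = "full", target = "O")
    base <- predict_cv(X, y, sim$cohort, fam, cfg)
    Xp <- X
    Xp[te, ] <- matrix(rnorm(length(te) * ncol(X)), length(te))
    pert <- predict_cv(Xp, y, sim$cohort, fam, cfg)
    k <- base$fold[te[1]]
    # masks, selected-edge counts and the chosen penalty are bytewise
    # identical: they are functions of the training fold only
    expect_identical(base$fold_info[[k]], pert$fold_info[[k]])
    # the held-out family's observed (deconfounded) scores are unchanged
    expect_identical(base$observed[te], pert$observed[te])
    # while its predictions do respond to its own edge values
    expect_false(isTRUE(all.equal(base$predicted[te], pert$predicted[te])))
  }
})

test_that("univariate predictions are invariant to global positive edge scaling", {
  sim <- generate_cohort(planted_spec(40, effect = 0.5, n_signal_edges = 20,
                                      n_parcels = 20, seed = 8))
  X <- unclass(generate_session_edges(sim$truth, "REST1"))
  y <- sim$cohort$trait_O
  cfg <- model_config("univariate_pos", deconfound_set = "none")
  r1 <- predict_cv(X, y, sim$cohort, sim$cohort$family_id, cfg)
  r2 <- predict_cv(2.5 * X, y, sim$cohort, sim$cohort$family_id, cfg)
  expect_equal(r1$predicted, r2$predicted, tolerance = 1e-8)
})
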