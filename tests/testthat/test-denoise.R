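# time-series operators and the three pipeline compositions

test_that("z-scoring normalizes, is idempotent, and drops dead channels", {
  set.seed(1)
  run <- make_run(matrix(rnorm(100 * 4, mean = 3, sd = 7), 100))
  z1 <- zscore_channels(run)
  expect_lt(max(abs(colMeans(z1$channels))), 1e-12)
  expect_lt(max(abs(apply(z1$channels, 2, sd) - 1)), 1e-12)
  z2 <- zscore_channels(z1)
  expect_equal(z2$channels, z1$channels)

  run$channels[, 2] <- 5   # constant parcel channel
  expect_warning(zd <- zscore_channels(run), "zero-variance")
  expect_equal(sum(zd$roles == "parcel"), 3)
})

test_that("Legendre detrending annihilates in-span drift, spares slow rhythms", {
  n_time <- 1200
  tt <- seq(-1, 1, length.out = n_time)
  cubic <- 2 + 3 * tt - tt^2 + 0.5 * tt^3
  run <- make_run(cbind(cubic, cubic + rnorm(n_time)))
  d <- legendre_detrend(run, degree = 3)
  expect_lt(max(abs(d$channels[, 1])), 1e-8)

  # residuals orthogonal to each Legendre regressor
  P <- connpred:::.legendre_design(n_time, 3)
  expect_lt(max(abs(crossprod(P, d$channels[, 1:2]))) / n_time, 1e-8)

  # a 0.05 Hz sinusoid over 1200 TRs of 0.72 s loses < 1% amplitude
  s <- sin(2 * pi * 0.05 * (0:(n_time - 1)) * 0.72)
  run2 <- make_run(cbind(s, s))
  d2 <- legendre_detrend(run2, degree = 3)
  att <- sqrt(sum(d2$channels[, 1]^2) / sum(s^2))
  expect_gt(att, 0.99)

  # raw drifting channel correlates with time; detrended does not
  drift_run <- make_run(cbind(rnorm(n_time) + 3 * tt, rnorm(n_time)))
  expect_gt(abs(cor(drift_run$channels[, 1], tt)), 0.8)
  d3 <- legendre_detrend(drift_run, degree = 3)
  expect_lt(abs(cor(d3$channels[, 1], tt)), 0.05)
})

test_that("nuisance regression is an OLS residualization of parcel channels", {
  set.seed(2)
  n_time <- 150
  noise <- matrix(rnorm(n_time * 3), n_time)
  run <- make_run(noise)
  # design = the channel itself: residual vanishes
  r1 <- regress_nuisance(run, cbind(run$channels[, 1]))
  expect_lt(max(abs(r1$channels[, 1])), 1e-10)
  # residuals orthogonal to all design columns
  design <- matrix(rnorm(n_time * 4), n_time)
  r2 <- regress_nuisance(run, design)
  expect_lt(max(abs(crossprod(design, r2$channels[, 1:3]))) / n_time, 1e-8)
  # design orthogonal to the channel: channel unchanged up to demeaning
  x <- rnorm(n_time)
  d_orth <- qr.resid(qr(cbind(1, x)), matrix(rnorm(n_time * 2), n_time))
  run3 <- make_run(cbind(x, rnorm(n_time)))
  r3 <- regress_nuisance(run3, d_orth)
  expect_equal(r3$channels[, 1], x - mean(x), tolerance = 1e-10,
               ignore_attr = TRUE)
  # collinear columns are dropped with a warning, not an error
  expect_warning(regress_nuisance(run, cbind(design, design[, 1])),
                 "collinear")
})

test_that("motion expansion yields 12 (mode A) or 24 (mode B) columns", {
  set.seed(3)
  motion <- matrix(rnorm(60 * 6), 60)
  expect_equal(ncol(expand_motion(motion, "A")), 12)
  expect_equal(ncol(expand_motion(motion, "B")), 24)
  expect_true(all(expand_motion(matrix(0, 60, 6), "B") == 0))
  # derivatives are backward differences with a leading zero
  ea <- expand_motion(motion, "A")
  expect_equal(ea[, 7], c(0, diff(motion[, 1])), ignore_attr = TRUE)
})

test_that("Gaussian low-pass matches its transfer-function oracle", {
  n_time <- 1200
  tr <- 0.72
  run <- make_run(cbind(rep(1, n_time) + 0, rnorm(n_time)))
  run$channels[, 1] <- 1
  g <- gaussian_lowpass(run, sd_s = tr)          # constant is unchanged
  expect_equal(g$channels[, 1], rep(1, n_time), tolerance = 1e-12,
               ignore_attr = TRUE)

  # sinusoid attenuation ~ continuous Gaussian transfer exp(-2 pi^2 f^2 sd^2)
  for (f_hz in c(0.05, 0.15)) {
    s <- sin(2 * pi * f_hz * (0:(n_time - 1)) * tr)
    rs <- make_run(cbind(s, s))
    gs <- gaussian_lowpass(rs, sd_s = tr)
    got <- sqrt(sum(gs$channels[100:1100, 1]^2) / sum(s[100:1100]^2))
    want <- exp(-2 * pi^2 * f_hz^2 * tr^2)
    expect_equal(got, want, tolerance = 0.02)
  }

  # white-noise variance shrinks by the kernel energy (discrete-kernel oracle)
  k <- dnorm(-4:4)
  k <- k / sum(k)
  set.seed(4)
  rn <- make_run(matrix(rnorm(20000 * 2), 20000))
  gn <- gaussian_lowpass(rn, sd_s = tr)
  expect_equal(var(gn$channels[, 1]), sum(k^2), tolerance = 0.05)
})

test_that("Butterworth band-pass keeps the band and kills DC", {
  n_time <- 2000
  tr <- 0.72
  tidx <- (0:(n_time - 1)) * tr
  amp_ratio <- function(f_hz) {
    s <- sin(2 * pi * f_hz * tidx)
    r <- make_run(cbind(s, s))
    b <- butter_bandpass(r, 1, 0.01, 0.08)
    mid <- 300:1700
    sqrt(sum(b$channels[mid, 1]^2) / sum(s[mid]^2))
  }
  # analytic zero-phase (|H|^2) first-order band-pass oracle
  oracle <- function(f_hz) {
    w <- 2 * pi * f_hz; w1 <- 2 * pi * 0.01; w2 <- 2 * pi * 0.08
    bw <- w2 - w1; w0sq <- w1 * w2
    (bw * w)^2 / ((w0sq - w^2)^2 + (bw * w)^2)
  }
  # continuous-time oracle; the bilinear design deviates slightly at high
  # normalized frequency, so compare on an absolute scale
  expect_lt(abs(amp_ratio(0.04) - oracle(0.04)), 0.03)
  expect_gte(amp_ratio(0.04), 0.90)
  expect_lt(abs(amp_ratio(0.2) - oracle(0.2)), 0.03)
  expect_lte(amp_ratio(0.2), 0.15)

  set.seed(5)
  r <- make_run(cbind(rnorm(500) + 10, rnorm(500)))
  b <- butter_bandpass(r, 1, 0.01, 0.08)
  expect_lt(abs(mean(b$channels[100:400, 1])), 0.05)  # DC gone (edge transients aside)

  r$censor_mask[] <- FALSE
  expect_error(butter_bandpass(r, 1, 0.01, 0.08), "censored")
})

test_that("censoring flags high-FD and high-DVARS volumes", {
  set.seed(6)
  run <- make_run(matrix(rnorm(3 * 4), 3))
  run$fd <- c(0.1, 0.3, 0.1)
  expect_equal(censor_volumes(run, 0.25), c(TRUE, FALSE, TRUE))

  # quiet run: nothing censored
  quiet <- make_run(matrix(rnorm(100 * 6), 100))
  quiet$fd <- rep(0.01, 100)
  expect_true(all(censor_volumes(quiet, 0.25)))

  # one spiked volume exceeds 1.05 x median DVARS and is censored
  spiked <- make_run(matrix(rnorm(100 * 6, sd = 0.1), 100))
  spiked$fd <- rep(0.01, 100)
  spiked$channels[40, spiked$roles == "parcel"] <-
    spiked$channels[40, spiked$roles == "parcel"] + 5
  mask <- censor_volumes(spiked, 0.25, dvars_ratio = 1.05)
  expect_false(mask[40])
  expect_false(mask[41])   # backward difference implicates the next frame too
  expect_true(mask[1])     # first frame never censored by the dvars criterion
})

test_that("CompCor extracts the shared WM/CSF subspace", {
  set.seed(7)
  n_time <- 300
  sources <- matrix(rnorm(n_time * 5), n_time)       # exact rank-5 space
  wm <- sources %*% matrix(rnorm(15), 5)
  csf <- sources %*% matrix(rnorm(10), 5)
  contaminated <- rnorm(n_time) + sources %*% rnorm(5)
  run <- make_run(cbind(contaminated, rnorm(n_time)), wm = wm, csf = csf)
  cc <- compcor(run, 5)
  expect_equal(dim(cc), c(n_time, 5L))
  expect_lt(max(abs(crossprod(cc) - diag(diag(crossprod(cc))))), 1e-8)

  resid <- qr.resid(qr(cbind(1, cc)), run$channels[, 1])
  removed <- 1 - var(resid) / var(run$channels[, 1])
  shared <- summary(lm(run$channels[, 1] ~ sources))$r.squared
  expect_gt(removed / shared, 0.999)

  expect_equal(ncol(compcor(run, 0)), 0L)
  expect_error(compcor(run, 6), "non-degenerate")
})

test_that("pipelines run their published step sequences deterministically", {
  sim <- generate_cohort(null_signal_spec(3, n_parcels = 12, seed = 10))
  run <- generate_run_timeseries(sim$cohort, sim$truth, "REST1_LR",
                                 n_timepoints = 240)[[1]]
  outA <- denoise(run, denoise_config("A"))
  expect_equal(attr(outA, "trace"),
               c("zscore", "legendre_detrend(deg=3,wm+csf)", "regress_csf_wm",
                 "regress_motion12", "gaussian_lowpass(sd=0.72s)",
                 "legendre_detrend(deg=3,parcel)", "regress_global"))
  # final GSR leaves parcels demeaned and orthogonal to the global channel
  gm <- outA$channels[, outA$roles == "parcel"]
  gs <- outA$channels[, outA$roles == "global"]
  expect_lt(max(abs(colMeans(gm))), 1e-8)
  expect_lt(max(abs(crossprod(gs, gm))) / nrow(gm), 1e-8)

  outB <- suppressWarnings(denoise(run, denoise_config("B")))
  expect_equal(attr(outB, "trace")[1:3],
               c("demean", "legendre_detrend(deg=2,parcel+wm+csf+global)",
                 "butter_bandpass(0.01-0.08 Hz)"))
  expect_true(all(outB$censor_mask))

  outC <- suppressWarnings(denoise(run, denoise_config("C")))
  expect_equal(attr(outC, "trace")[4], "butter_bandpass(0.01-0.08 Hz)")

  # shapes preserved; censoring is a mask, not a deletion
  for (out in list(outA, outB, outC)) {
    expect_equal(sum(out$roles == "parcel"), 12)
    expect_equal(nrow(out$channels), 240)
  }
  # determinism: identical input, identical output bits
  outA2 <- denoise(run, denoise_config("A"))
  expect_identical(outA$channels, outA2$channels)

  bad <- run
  keep <- bad$roles != "global"
  bad$channels <- bad$channels[, keep]
  bad$roles <- bad$roles[keep]
  expect_error(denoise(bad, denoise_config("A")), "global")
})

test_that("pipeline B confines white-noise power to the passband", {
  set.seed(11)
  sim <- generate_cohort(null_signal_spec(2, n_parcels = 8, seed = 12,
                                          fingerprint_share = 0))
  run <- generate_run_timeseries(sim$cohort, sim$truth, "REST1_LR",
                                 n_timepoints = 1024, clean = TRUE)[[1]]
  out <- suppressWarnings(denoise(run, denoise_config("B")))
  x <- out$channels[, which(out$roles == "parcel")[1]]
  pw <- Mod(fft(x - mean(x)))^2
  freq <- (seq_along(pw) - 1) / (length(pw) * run$tr_s)
  half <- freq <= 1 / (2 * run$tr_s)
  inband <- half & freq >= 0.01 & freq <= 0.08
  # zero-phase order-1 Butterworth shoulders put a bounded share of the
  # output power outside the nominal band
  expect_lt(sum(pw[half & !inband]) / sum(pw[half]), 0.35)
  expect_gt(sum(pw[inband]) / sum(pw[half]), 0.65)
})
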