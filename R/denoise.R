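# Denoising of parcellated BOLD runs: labeled time-series operators (z-score,
# polynomial/Legendre detrending, nuisance regression, motion expansion,
# Gaussian low-pass, zero-phase Butterworth band-pass, censoring, CompCor)
# composed into three published pipelines (A, B, C).

#' Denoising configuration
#'
#' @param pipeline `"A"`, `"B"` or `"C"`.
#' @param legendre_degree degree of the Legendre detrend (pipelines A).
#' @param gaussian_sd_s SD of the Gaussian low-pass kernel in seconds
#'   (pipeline A; default one TR of the reference acquisition).
#' @param butter_order Butterworth filter order (pipelines B, C).
#' @param passband_hz band-pass limits in Hz (pipelines B, C).
#' @param fd_censor_mm framewise-displacement censoring threshold in mm.
#' @param dvars_censor_ratio censor volumes whose DVARS exceeds this multiple
#'   of the run-median DVARS (pipeline C).
#' @param compcor_k number of CompCor components (pipeline C).
#' @export
denoise_config <- function(pipeline = c("A", "B", "C"),
                           legendre_degree = 3,
                           gaussian_sd_s = 0.72,
                           butter_order = 1,
                           passband_hz = c(0.01, 0.08),
                           fd_censor_mm = 0.25,
                           dvars_censor_ratio = 1.05,
                           compcor_k = 5) {
  pipeline <- match.arg(pipeline)
  .assert(legendre_degree >= 0, "legendre_degree must be >= 0")
  .assert(length(passband_hz) == 2 && passband_hz[1] < passband_hz[2],
          "passband_hz must be (low, high) with low < high")
  structure(list(pipeline = pipeline, legendre_degree = legendre_degree,
                 gaussian_sd_s = gaussian_sd_s, butter_order = butter_order,
                 passband_hz = passband_hz, fd_censor_mm = fd_censor_mm,
                 dvars_censor_ratio = dvars_censor_ratio,
                 compcor_k = compcor_k),
            class = "denoise_config")
}

.trace_step <- function(run, label) {
  attr(run, "trace") <- c(attr(run, "trace"), label)
  run
}

.role_cols <- function(run, roles) which(run$roles %in% roles)

.check_run <- function(run) {
  .assert(inherits(run, "run_timeseries"), "expected a run_timeseries object")
  invisible(run)
}

#' z-score normalize channels
#'
#' Each targeted channel is centered and scaled to unit sample SD.
#' Zero-variance channels are dropped with a warning.
#'
#' @param run a `run_timeseries`.
#' @param roles channel roles to normalize (default: all).
#' @export
zscore_channels <- function(run, roles = unique(run$roles)) {
  .check_run(run)
  cols <- .role_cols(run, roles)
  v <- apply(run$channels[, cols, drop = FALSE], 2, stats::sd)
  dead <- cols[v == 0]
  if (length(dead) > 0) {
    .warnf("dropping %d zero-variance channel(s): %s", length(dead),
           paste(colnames(run$channels)[dead], collapse = ", "))
    run$channels <- run$channels[, -dead, drop = FALSE]
    run$roles <- run$roles[-dead]
    cols <- .role_cols(run, roles)
  }
  run$channels[, cols] <- scale(run$channels[, cols, drop = FALSE])
  .trace_step(run, "zscore")
}

# orthonormal-ish Legendre polynomial design P0..Pk on [-1, 1]
.legendre_design <- function(n_time, degree) {
  x <- seq(-1, 1, length.out = n_time)
  P <- matrix(1, n_time, degree + 1)
  if (degree >= 1) P[, 2] <- x
  if (degree >= 2) {
    for (k in 2:degree) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}

#' Remove temporal drifts with Legendre polynomial regressors
#'
#' Least-squares residual of each targeted channel on Legendre polynomials
#' P0..P_degree evaluated on `[-1, 1]` over the run.
#'
#' @param run a `run_timeseries`.
#' @param degree polynomial degree.
#' @param roles channel roles to detrend.
#' @export
legendre_detrend <- function(run, degree = 3, roles = "parcel") {
  .check_run(run)
  n_time <- nrow(run$channels)
  .assert(n_time >= degree + 2, "need at least degree + 2 time points")
  P <- .legendre_design(n_time, degree)
  cols <- .role_cols(run, roles)
  run$channels[, cols] <- stats::lm.fit(P, run$channels[, cols, drop = FALSE])$residuals
  .trace_step(run, sprintf("legendre_detrend(deg=%d,%s)", degree,
                           paste(roles, collapse = "+")))
}

#' Ordinary least-squares nuisance regression
#'
#' Residualizes the targeted channels on the design columns (an intercept is
#' always included). Collinear design columns are dropped by pivoting with a
#' warning.
#'
#' @param run a `run_timeseries`.
#' @param design numeric matrix of nuisance regressors (time x k).
#' @param roles channel roles to residualize (default parcels).
#' @param label trace label.
#' @param fit_mask optional logical mask: coefficients are estimated on these
#'   time points only, residuals formed everywhere.
#' @export
regress_nuisance <- function(run, design, roles = "parcel",
                             label = "regress_nuisance", fit_mask = NULL) {
  .check_run(run)
  X <- cbind(`(Intercept)` = 1, design)
  cols <- .role_cols(run, roles)
  Y <- run$channels[, cols, drop = FALSE]
  qrX <- qr(if (is.null(fit_mask)) X else X[fit_mask, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    .warnf("%d collinear design column(s) dropped", ncol(X) - qrX$rank)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, keep, drop = FALSE]
    qrX <- qr(if (is.null(fit_mask)) X else X[fit_mask, , drop = FALSE])
  }
  beta <- qr.coef(qrX, if (is.null(fit_mask)) Y else Y[fit_mask, , drop = FALSE])
  beta[is.na(beta)] <- 0
  run$channels[, cols] <- Y - X %*% beta
  .trace_step(run, label)
}

#' Expand realignment parameters into a motion design
#'
#' Mode `"A"`: the six parameters and their temporal derivatives (12
#' columns). Mode `"B"`: parameters, derivatives, squared parameters, and
#' squared derivatives (24 columns). Derivatives are backward differences
#' with a leading zero row.
#'
#' @param motion time x 6 matrix of realignment parameters.
#' @param mode `"A"` (12 columns) or `"B"` (24 columns).
#' @export
expand_motion <- function(motion, mode = c("A", "B")) {
  mode <- match.arg(mode)
  .assert(is.matrix(motion) && ncol(motion) == 6, "motion must be time x 6")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d)
  if (mode == "B") out <- cbind(out, motion^2, d^2)
  colnames(out) <- paste0("mot", seq_len(ncol(out)))
  out
}

# unit-sum Gaussian kernel smoothing with reflect padding
.gaussian_smooth <- function(x, sd_samples) {
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[half:1], x, x[n:(n - half + 1)])
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + n)]
}

#' Gaussian low-pass temporal filter
#'
#' Convolution with a unit-sum Gaussian kernel of SD `sd_s` seconds
#' (truncated at +-4 SD, reflect-padded at the run boundaries).
#'
#' @param run a `run_timeseries`.
#' @param sd_s kernel SD in seconds.
#' @param roles channel roles to filter.
#' @export
gaussian_lowpass <- function(run, sd_s = 0.72,
                             roles = c("parcel", "wm", "csf", "global")) {
  .check_run(run)
  .assert(sd_s > 0, "sd_s must be > 0")
  sd_samples <- sd_s / run$tr_s
  cols <- .role_cols(run, roles)
  run$channels[, cols] <- apply(run$channels[, cols, drop = FALSE], 2,
                                .gaussian_smooth, sd_samples = sd_samples)
  .trace_step(run, sprintf("gaussian_lowpass(sd=%gs)", sd_s))
}

# linear interpolation across censored time points (edges held constant)
.interp_censored <- function(x, keep) {
  if (all(keep)) return(x)
  .assert(any(keep), "all volumes censored; cannot interpolate")
  idx <- seq_along(x)
  stats::approx(idx[keep], x[keep], xout = idx, rule = 2)$y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Censored time points are first linearly interpolated from the nearest
#' retained neighbors (run edges held constant), then a forward-backward
#' (zero-phase) Butterworth band-pass is applied.
#'
#' @param run a `run_timeseries`.
#' @param order filter order.
#' @param low_hz,high_hz passband limits; `high_hz` must be below Nyquist.
#' @param censor_mask logical retained-volume mask (default: the run's own).
#' @param roles channel roles to filter.
#' @export
butter_bandpass <- function(run, order = 1, low_hz = 0.01, high_hz = 0.08,
                            censor_mask = run$censor_mask,
                            roles = c("parcel", "wm", "csf", "global")) {
  .check_run(run)
  nyq <- 1 / (2 * run$tr_s)
  .assert(low_hz > 0 && low_hz < high_hz && high_hz < nyq,
          "need 0 < low < high < Nyquist (%.3f Hz)", nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  cols <- .role_cols(run, roles)
  run$channels[, cols] <- apply(run$channels[, cols, drop = FALSE], 2,
                                function(x) {
                                  signal::filtfilt(bf, .interp_censored(x, censor_mask))
                                })
  .trace_step(run, sprintf("butter_bandpass(%g-%g Hz)", low_hz, high_hz))
}

#' Per-timepoint DVARS
#'
#' Variance across parcel channels of the backward-differenced signal; the
#' first time point gets the run-median value (it is never censored by the
#' difference criterion).
#'
#' @param run a `run_timeseries`.
#' @export
dvars <- function(run) {
  .check_run(run)
  x <- run$channels[, .role_cols(run, "parcel"), drop = FALSE]
  d <- diff(x)
  v <- apply(d, 1, stats::var)
  c(stats::median(v), v)
}

#' Censoring mask from FD and (optionally) DVARS
#'
#' Marks volumes for removal when framewise displacement exceeds
#' `fd_thresh_mm`, or (if `dvars_ratio` is given) when DVARS exceeds
#' `dvars_ratio` times the run-median DVARS. `TRUE` = retained.
#'
#' @param run a `run_timeseries`.
#' @param fd_thresh_mm FD threshold in mm.
#' @param dvars_ratio multiple of the median DVARS, or `NULL` to skip.
#' @export
censor_volumes <- function(run, fd_thresh_mm = 0.25, dvars_ratio = NULL) {
  .check_run(run)
  bad <- run$fd > fd_thresh_mm
  if (!is.null(dvars_ratio)) {
    dv <- dvars(run)
    bad_dv <- dv > dvars_ratio * stats::median(dv[-1])
    bad_dv[1] <- FALSE
    bad <- bad | bad_dv
  }
  !bad
}

#' CompCor nuisance components
#'
#' Top-`k` principal component time courses of the pooled, demeaned,
#' variance-normalized white-matter and CSF channels.
#'
#' @param run a `run_timeseries`.
#' @param k number of components.
#' @export
compcor <- function(run, k = 5) {
  .check_run(run)
  if (k == 0) return(matrix(0, nrow(run$channels), 0))
  x <- run$channels[, .role_cols(run, c("wm", "csf")), drop = FALSE]
  v <- apply(x, 2, stats::sd)
  x <- x[, v > 0, drop = FALSE]
  .assert(ncol(x) >= k, "need at least k = %d non-degenerate WM/CSF channels", k)
  .assert(nrow(x) > k, "need more time points than components")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pc$x[, seq_len(k), drop = FALSE]
}

# backward difference with leading zero, and quadratic expansion helpers
.bdiff <- function(x) {
  if (is.matrix(x)) rbind(0, diff(x)) else c(0, diff(x))
}

.tissue_means <- function(run) {
  ch <- run$channels
  list(wm = rowMeans(ch[, .role_cols(run, "wm"), drop = FALSE]),
       csf = rowMeans(ch[, .role_cols(run, "csf"), drop = FALSE]),
       gm = rowMeans(ch[, .role_cols(run, "parcel"), drop = FALSE]),
       gs = ch[, .role_cols(run, "global"), drop = FALSE][, 1])
}

.demean_channels <- function(run) {
  run$channels <- scale(run$channels, center = TRUE, scale = FALSE)
  .trace_step(run, "demean")
}

.poly_detrend <- function(run, degree, roles = unique(run$roles)) {
  run <- legendre_detrend(run, degree = degree, roles = roles)
  run  # Legendre P0..Pk spans the same space as raw polynomials 1..t^k
}

.require_roles <- function(run, roles) {
  missing <- setdiff(roles, unique(run$roles))
  .assert(length(missing) == 0, "run lacks required channel role(s): %s",
          paste(missing, collapse = ", "))
}

.denoise_A <- function(run, config) {
  .require_roles(run, c("parcel", "wm", "csf", "global"))
  run <- zscore_channels(run)
  run <- legendre_detrend(run, config$legendre_degree, roles = c("wm", "csf"))
  tm <- .tissue_means(run)
  run <- regress_nuisance(run, cbind(csf = tm$csf, wm = tm$wm),
                          label = "regress_csf_wm")
  run <- regress_nuisance(run, expand_motion(run$motion, "A"),
                          label = "regress_motion12")
  run <- gaussian_lowpass(run, config$gaussian_sd_s,
                          roles = c("parcel", "global"))
  run <- legendre_detrend(run, config$legendre_degree, roles = "parcel")
  gs <- run$channels[, .role_cols(run, "global"), drop = FALSE][, 1]
  run <- regress_nuisance(run, cbind(gs = gs), label = "regress_global")
  run$censor_mask <- rep(TRUE, nrow(run$channels))
  run
}

.denoise_B <- function(run, config) {
  .require_roles(run, c("parcel", "wm", "csf", "global"))
  run <- .demean_channels(run)
  run <- .poly_detrend(run, 2)
  mask <- censor_volumes(run, config$fd_censor_mm)
  run <- butter_bandpass(run, config$butter_order, config$passband_hz[1],
                         config$passband_hz[2], censor_mask = mask)
  tm <- .tissue_means(run)
  expand_tissue <- function(x) cbind(x, .bdiff(x), x^2)
  design <- cbind(expand_tissue(tm$csf), expand_tissue(tm$wm),
                  expand_motion(run$motion, "B"), expand_tissue(tm$gs))
  # filter nuisance columns like the data before the combined regression
  nyq <- 1 / (2 * run$tr_s)
  bf <- signal::butter(config$butter_order, config$passband_hz / nyq, "pass")
  design <- apply(design, 2,
                  function(x) signal::filtfilt(bf, .interp_censored(x, mask)))
  if (any(!mask)) {       # one spike regressor per censored volume
    spikes <- outer(seq_along(mask), which(!mask), `==`) * 1
    design <- cbind(design, spikes)
  }
  run <- regress_nuisance(run, design, label = "regress_combined")
  run$censor_mask <- rep(TRUE, nrow(run$channels))  # volumes retained: censoring
  run                                               # was absorbed by the spikes
}

.denoise_C <- function(run, config) {
  .require_roles(run, c("parcel", "wm", "csf", "global"))
  run <- .demean_channels(run)
  run <- .poly_detrend(run, 1)
  mask <- censor_volumes(run, config$fd_censor_mm, config$dvars_censor_ratio)
  tm <- .tissue_means(run)
  design <- cbind(compcor(run, config$compcor_k), gm = tm$gm, gs = tm$gs)
  run <- regress_nuisance(run, design, label = "regress_compcor_gm_gs",
                          fit_mask = mask)
  run <- butter_bandpass(run, config$butter_order, config$passband_hz[1],
                         config$passband_hz[2], censor_mask = mask)
  run$censor_mask <- mask   # censored volumes are discarded downstream (FC)
  run
}

#' Run a denoising pipeline on one run
#'
#' Executes the configured pipeline's steps in their published order.
#' Pipeline A: z-score; Legendre-3 detrend of CSF/WM; regression of mean
#' CSF/WM from parcels; 12-parameter motion regression; Gaussian low-pass;
#' Legendre-3 detrend of parcels; global-signal regression. Pipeline B:
#' demean; linear+quadratic detrend; 0.01-0.08 Hz band-pass (censored
#' volumes interpolated first); one combined regression of tissue signals
#' (+derivative +quadratic), 24-parameter motion, global signal (+derivative
#' +quadratic) and one spike regressor per censored volume. Pipeline C
#' (expects component-cleaned input): demean; linear detrend; regression of
#' 5 CompCor components plus gray-matter and whole-brain means, fitted on
#' retained volumes; band-pass with interpolation; censored volumes stay
#' flagged for exclusion from FC.
#'
#' An execution trace is carried in `attr(run, "trace")`.
#'
#' @param run a `run_timeseries`.
#' @param config a [denoise_config()].
#' @export
denoise <- function(run, config = denoise_config("A")) {
  .check_run(run)
  .assert(inherits(config, "denoise_config"), "config must come from denoise_config()")
  attr(run, "trace") <- character(0)
  switch(config$pipeline,
         A = .denoise_A(run, config),
         B = .denoise_B(run, config),
         C = .denoise_C(run, config))
}
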