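# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes -- family structure, Big Five latent traits with realistic
# intercorrelations, confounds correlated with traits and with designated FC
# edges, subject-stable connectome fingerprints with a family-shared part,
# planted trait-linked edges, and per-run parcellated BOLD-like time series
# with motion/drift artifacts -- so that every downstream stage can be tested
# against known ground truth.

#' Default Big Five intercorrelation matrix
#'
#' Emulates the intercorrelation pattern typical of NEO-FFI samples:
#' Neuroticism anticorrelated with Conscientiousness, Extraversion and
#' Agreeableness; those three positively intercorrelated; Openness only
#' weakly related to the rest. Order: O, C, E, A, N.
#'
#' @export
default_trait_cor <- function() {
  s <- diag(5)
  dimnames(s) <- list(NEO_FACTORS, NEO_FACTORS)
  set_r <- function(a, b, r) {
    s[a, b] <<- r
    s[b, a] <<- r
  }
  set_r("O", "C", -0.05); set_r("O", "E", 0.10); set_r("O", "A", 0.05)
  set_r("O", "N", -0.05); set_r("C", "E", 0.25); set_r("C", "A", 0.25)
  set_r("C", "N", -0.41); set_r("E", "A", 0.22); set_r("E", "N", -0.34)
  set_r("A", "N", -0.28)
  s
}

#' Default confound model
#'
#' Each confound gets (a) target correlations with latent traits and (b) a
#' set of FC edges it directly perturbs, emulating the confound -> FC paths
#' (sex, age, head motion, brain size, reconstruction version, fluid
#' intelligence) that deconfounding is meant to remove.
#'
#' @export
default_confound_effects <- function() {
  list(
    gender        = list(trait_r = c(O = -0.15, C = 0.15, A = 0.25, N = 0.20),
                         n_edges = 150, edge_r = 0.15),
    age           = list(trait_r = c(O = -0.10, A = 0.10),
                         n_edges = 100, edge_r = 0.10),
    handedness    = list(trait_r = c(), n_edges = 0, edge_r = 0),
    brain_size    = list(trait_r = c(O = 0.10, N = -0.10),
                         n_edges = 100, edge_r = 0.10),
    motion        = list(trait_r = c(O = -0.10),
                         n_edges = 150, edge_r = 0.20),
    recon_version = list(trait_r = c(O = 0.08),
                         n_edges = 150, edge_r = 0.15),
    gF            = list(trait_r = c(O = 0.25, C = -0.10, E = -0.10, N = -0.10),
                         n_edges = 100, edge_r = 0.15)
  )
}

#' Latent trait model for the synthetic cohort
#'
#' @param trait_intercorrelation 5 x 5 positive-semidefinite correlation
#'   matrix of the latent Big Five (unit diagonal).
#' @param item_noise_sd SD of the per-item Gaussian noise added to the latent
#'   trait before Likert discretization, in latent-trait SD units. The
#'   default 1.5 places Cronbach's alpha of the 12-item factor scales in the
#'   high-0.7s/low-0.8s, the reliability regime reported for the NEO-FFI.
#' @param signal_edges_per_trait number of FC edges carrying each trait's
#'   signal (disjoint across traits).
#' @param signal_effect per-trait correlation magnitude between a signal edge
#'   and the trait, in `[0, 1]`; scalar is recycled to all five traits.
#' @export
latent_trait_model <- function(trait_intercorrelation = default_trait_cor(),
                               item_noise_sd = 1.5,
                               signal_edges_per_trait = 100,
                               signal_effect = 0.2) {
  s <- trait_intercorrelation
  .assert(is.matrix(s) && all(dim(s) == 5), "trait_intercorrelation must be 5 x 5")
  .assert(max(abs(s - t(s))) < 1e-12 && all(abs(diag(s) - 1) < 1e-12),
          "trait_intercorrelation must be symmetric with unit diagonal")
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) > -1e-10,
          "trait_intercorrelation is not positive semidefinite (min eigenvalue %g)",
          min(ev))
  .assert(item_noise_sd >= 0, "item_noise_sd must be >= 0")
  eff <- rep_len(signal_effect, 5)
  .assert(all(eff >= 0 & eff <= 1), "signal_effect must lie in [0, 1]")
  structure(list(trait_intercorrelation = s,
                 item_noise_sd = item_noise_sd,
                 signal_edges_per_trait = signal_edges_per_trait,
                 signal_effect = stats::setNames(eff, NEO_FACTORS)),
            class = "latent_trait_model")
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param n_families number of families; defaults to the empirical
#'   subjects-per-family ratio of the reference cohort (about 2.2).
#' @param family_size_dist named probability vector over family sizes >= 1
#'   used to draw family sizes (then adjusted to partition `n_subjects`).
#' @param trait_model a [latent_trait_model()].
#' @param confound_effects confound model, see [default_confound_effects()].
#' @param fingerprint_share fraction in `[0, 1]` of (non-group) FC edge
#'   variance that is subject-stable across sessions; the remainder is
#'   session noise.
#' @param familial_fc_share fraction in `[0, 1]` of the stable FC variance
#'   that is shared within family.
#' @param familial_trait_rho correlation of latent traits between members of
#'   the same family.
#' @param n_parcels number of parcels for the FC ground truth.
#' @param edge_sd between-subject SD of an edge's Fisher-z value.
#' @param run_noise_sd additional run-level Fisher-z noise on top of the
#'   session-level target FC.
#' @param seed integer seed; all generation is deterministic given the spec.
#' @export
cohort_spec <- function(n_subjects,
                        n_families = max(1L, round(n_subjects / 2.16)),
                        family_size_dist = c(`1` = 0.25, `2` = 0.40, `3` = 0.35),
                        trait_model = latent_trait_model(),
                        confound_effects = default_confound_effects(),
                        fingerprint_share = 0.5,
                        familial_fc_share = 0.3,
                        familial_trait_rho = 0.5,
                        n_parcels = 60,
                        edge_sd = 0.2,
                        run_noise_sd = 0.02,
                        seed = 1) {
  .assert(n_subjects >= 1, "n_subjects must be >= 1")
  .assert(n_families >= 1 && n_families <= n_subjects,
          "impossible family partition: n_families=%d for n_subjects=%d",
          n_families, n_subjects)
  for (nm in c("fingerprint_share", "familial_fc_share", "familial_trait_rho")) {
    val <- get(nm)
    .assert(val >= 0 && val <= 1, "%s must lie in [0, 1] (got %g)", nm, val)
  }
  .assert(all(family_size_dist >= 0) && sum(family_size_dist) > 0,
          "family_size_dist must be a non-negative probability vector")
  .assert(inherits(trait_model, "latent_trait_model"),
          "trait_model must come from latent_trait_model()")
  .assert(n_parcels >= 2, "n_parcels must be >= 2")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_families = as.integer(n_families),
                 family_size_dist = family_size_dist,
                 trait_model = trait_model,
                 confound_effects = confound_effects,
                 fingerprint_share = fingerprint_share,
                 familial_fc_share = familial_fc_share,
                 familial_trait_rho = familial_trait_rho,
                 n_parcels = as.integer(n_parcels),
                 edge_sd = edge_sd,
                 run_noise_sd = run_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw family sizes from the size distribution, then adjust to sum exactly to
# n_subjects while keeping every size >= 1
.partition_families <- function(n_subjects, n_families, size_dist) {
  sizes_vals <- as.integer(names(size_dist))
  .assert(!anyNA(sizes_vals) && all(sizes_vals >= 1),
          "family_size_dist names must be integer sizes >= 1")
  sizes <- sizes_vals[sample.int(length(sizes_vals), n_families,
                                 replace = TRUE, prob = size_dist)]
  max_size <- max(sizes_vals)
  excess <- sum(sizes) - n_subjects
  while (excess > 0) {
    k <- which(sizes > 1)
    .assert(length(k) > 0,
            "impossible family partition: %d families cannot hold %d subjects",
            n_families, n_subjects)
    take <- k[which.max(sizes[k])]
    sizes[take] <- sizes[take] - 1L
    excess <- excess - 1L
  }
  while (excess < 0) {
    k <- which(sizes < max_size)
    .assert(length(k) > 0,
            "impossible family partition: %d families of size <= %d cannot hold %d subjects",
            n_families, max_size, n_subjects)
    take <- k[which.min(sizes[k])]
    sizes[take] <- sizes[take] + 1L
    excess <- excess + 1L
  }
  sizes
}

.rmvnorm_chol <- function(n, sigma) {
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% chol(sigma)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws family structure, latent Big Five traits (family-correlated,
#' intercorrelated per the trait model), confounds correlated with traits,
#' inclusion-relevant fields (MMSE, completeness flags, per-run motion RMS),
#' and the FC ground-truth components (group mean, family-shared and
#' subject-stable fingerprints, planted trait- and confound-linked edges).
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (data frame, one row per subject) and `truth`
#'   (a `ground_truth` object consumed by [generate_session_edges()] and
#'   [generate_run_timeseries()]).
#' @export
generate_cohort <- function(spec) {
  .assert(inherits(spec, "cohort_spec"), "spec must come from cohort_spec()")
  set.seed(spec$seed)
  n <- spec$n_subjects
  tm <- spec$trait_model

  sizes <- .partition_families(n, spec$n_families, spec$family_size_dist)
  family_index <- rep(seq_along(sizes), times = sizes)
  subject_id <- sprintf("S%04d", seq_len(n))
  family_id <- sprintf("F%04d", family_index)

  # latent traits: family component + individual component, both MVN with the
  # specified intercorrelation; sibling correlation = familial_trait_rho
  sigma <- tm$trait_intercorrelation
  rho <- spec$familial_trait_rho
  fam_t <- .rmvnorm_chol(spec$n_families, sigma)
  ind_t <- .rmvnorm_chol(n, sigma)
  traits <- sqrt(rho) * fam_t[family_index, , drop = FALSE] + sqrt(1 - rho) * ind_t
  colnames(traits) <- NEO_FACTORS

  # confound latents: weighted trait mixture plus independent noise, so that
  # cor(latent, trait_k) equals the requested trait_r
  ce <- spec$confound_effects
  conf_latent <- vapply(names(ce), function(nm) {
    w <- ce[[nm]]$trait_r
    lat <- stats::rnorm(n)
    if (length(w) > 0) {
      wn2 <- sum(w^2)
      .assert(wn2 < 1, "confound %s: squared trait correlations exceed 1", nm)
      lat <- traits[, names(w), drop = FALSE] %*% w + sqrt(1 - wn2) * lat
    }
    as.numeric(lat)
  }, numeric(n))
  conf_latent <- matrix(conf_latent, nrow = n,
                        dimnames = list(NULL, names(ce)))

  motion_lat <- conf_latent[, "motion"]
  run_rms <- exp(log(0.07) + 0.30 * motion_lat +
                   matrix(stats::rnorm(n * 4, sd = 0.25), n, 4))
  colnames(run_rms) <- paste0("run_motion_rms_", 1:4)

  cohort <- data.frame(
    subject_id = subject_id,
    family_id = family_id,
    gender = as.integer(conf_latent[, "gender"] > 0),
    age = round(22 + 14 * stats::pnorm(conf_latent[, "age"])),
    handedness = round(100 * (2 * stats::pnorm(conf_latent[, "handedness"]) - 1)),
    brain_size = round(1.18e6 + 1.1e5 * conf_latent[, "brain_size"]),
    motion_rest1 = exp(log(60) + 0.4 * (0.85 * motion_lat +
                                          sqrt(1 - 0.85^2) * stats::rnorm(n))),
    motion_rest2 = exp(log(60) + 0.4 * (0.85 * motion_lat +
                                          sqrt(1 - 0.85^2) * stats::rnorm(n))),
    recon_version = as.integer(conf_latent[, "recon_version"] > stats::qnorm(0.45)),
    gF = pmin(24, pmax(0, round(17 + 5 * conf_latent[, "gF"]))),
    mmse = 30L - stats::rbinom(n, 8, 0.08),
    behavior_complete = stats::rbinom(n, 1, 0.98) == 1,
    fmri_complete = stats::rbinom(n, 1, 0.85) == 1,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(run_rms))
  for (f in NEO_FACTORS) cohort[[paste0("trait_", f)]] <- traits[, f]
  class(cohort) <- c("cohort", "data.frame")

  # FC ground truth
  ne <- n_edges(spec$n_parcels)
  mu <- stats::rnorm(ne, mean = 0.25, sd = 0.15)
  fam_comp <- matrix(stats::rnorm(spec$n_families * ne), spec$n_families, ne)
  sub_comp <- matrix(stats::rnorm(n * ne), n, ne)

  # disjoint signal / confound edge sets; scaled down proportionally when the
  # requested sets would use more than 60% of the connectome
  want_signal <- vapply(NEO_FACTORS, function(f) {
    if (tm$signal_effect[[f]] > 0) as.integer(tm$signal_edges_per_trait) else 0L
  }, 1L)
  want_conf <- vapply(ce, function(x) {
    if (x$edge_r > 0) as.integer(x$n_edges) else 0L
  }, 1L)
  budget <- floor(0.6 * ne)
  total <- sum(want_signal) + sum(want_conf)
  if (total > budget) {
    shrink <- budget / total
    .warnf("signal/confound edge sets scaled by %.2f to fit %d edges",
           shrink, ne)
    rescale <- function(k) stats::setNames(as.integer(floor(k * shrink)), names(k))
    want_signal <- rescale(want_signal)
    want_conf <- rescale(want_conf)
  }
  pool <- sample.int(ne)
  take <- function(k) {
    if (k == 0) return(integer(0))
    .assert(k <= length(pool), "not enough edges for the requested signal sets")
    out <- sort(pool[seq_len(k)])
    pool <<- pool[-seq_len(k)]
    out
  }
  signal <- lapply(NEO_FACTORS, function(f) {
    list(edges = take(want_signal[[f]]), effect = tm$signal_effect[[f]])
  })
  names(signal) <- NEO_FACTORS
  confound_edges <- lapply(names(ce), function(nm) {
    list(edges = take(want_conf[[nm]]), effect = ce[[nm]]$edge_r,
         latent = as.numeric(scale(conf_latent[, nm])))
  })
  names(confound_edges) <- names(ce)

  truth <- structure(list(
    seed = spec$seed,
    n_parcels = spec$n_parcels,
    n_edges = ne,
    edge_sd = spec$edge_sd,
    run_noise_sd = spec$run_noise_sd,
    fingerprint_share = spec$fingerprint_share,
    familial_fc_share = spec$familial_fc_share,
    mu = mu,
    fam_comp = fam_comp,
    sub_comp = sub_comp,
    family_index = family_index,
    traits = traits,
    signal = signal,
    confound_edges = confound_edges
  ), class = "ground_truth")

  list(cohort = cohort, truth = truth)
}

# standardized structured component of every edge for one session:
# family + subject stable parts (fingerprint) plus session noise, with trait
# and confound signal mixed into their designated edges at the target
# correlation
.session_component <- function(truth, session_noise) {
  fp <- truth$fingerprint_share
  ff <- truth$familial_fc_share
  stable <- sqrt(ff) * truth$fam_comp[truth$family_index, , drop = FALSE] +
    sqrt(1 - ff) * truth$sub_comp
  base <- sqrt(fp) * stable + sqrt(1 - fp) * session_noise
  mix_in <- function(base, edges, effect, x) {
    if (length(edges) == 0 || effect == 0) return(base)
    base[, edges] <- effect * x +
      sqrt(1 - effect^2) * base[, edges, drop = FALSE]
    base
  }
  for (f in NEO_FACTORS) {
    sg <- truth$signal[[f]]
    base <- mix_in(base, sg$edges, sg$effect, truth$traits[, f])
  }
  for (nm in names(truth$confound_edges)) {
    cf <- truth$confound_edges[[nm]]
    base <- mix_in(base, cf$edges, cf$effect, cf$latent)
  }
  base
}

.session_number <- function(session) {
  match(session, c("REST1", "REST2"))
}

#' Session-level target FC edge matrix
#'
#' Returns every subject's target Fisher-z edge vector for one session:
#' group mean + family-shared + subject-stable fingerprint + session noise,
#' with the planted trait/confound signal on its designated edges. This is
#' the FC a run's empirical connectome converges to as the number of time
#' points grows. Deterministic given the ground truth.
#'
#' @param truth `ground_truth` from [generate_cohort()].
#' @param session `"REST1"` or `"REST2"`.
#' @return an `edge_matrix` (subjects x edges, Fisher-z scale).
#' @export
generate_session_edges <- function(truth, session = c("REST1", "REST2")) {
  session <- match.arg(session)
  .assert(inherits(truth, "ground_truth"), "truth must come from generate_cohort()")
  n <- nrow(truth$sub_comp)
  set.seed((truth$seed %% 1000003L) * 2L + .session_number(session))
  noise <- matrix(stats::rnorm(n * truth$n_edges), n, truth$n_edges)
  z <- sweep(truth$edge_sd * .session_component(truth, noise), 2, truth$mu, "+")
  rownames(z) <- sprintf("S%04d", seq_len(n))
  structure(z, class = c("edge_matrix", "matrix"), session = session)
}

# clip eigenvalues so tanh(z) is a usable correlation matrix and renormalize
# to unit diagonal; per-edge z targets are generated freely, so the matrix
# they imply need not be positive semidefinite -- this projection is what the
# sampled time series actually converge to
.nearest_corr <- function(r, eps = 1e-4) {
  eg <- eigen(r, symmetric = TRUE)
  vals <- pmax(eg$values, eps)
  m <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(m))
  m / tcrossprod(d)
}

.chol_nearest_corr <- function(r, eps = 1e-4) chol(.nearest_corr(r, eps))

#' Target correlation matrix of one subject's session
#'
#' The population correlation matrix that [generate_run_timeseries()] samples
#' from (before run-level jitter): `tanh` of the subject's session edge
#' vector, projected to the nearest valid (positive-semidefinite,
#' unit-diagonal) correlation matrix. Empirical run FC converges to this
#' matrix as the number of time points grows.
#'
#' @param truth `ground_truth` from [generate_cohort()].
#' @param session `"REST1"` or `"REST2"`.
#' @param subject subject row index.
#' @export
target_fc <- function(truth, session = c("REST1", "REST2"), subject = 1) {
  session <- match.arg(session)
  z <- generate_session_edges(truth, session)[subject, ]
  r <- tanh(unvectorize(z, truth$n_parcels))
  diag(r) <- 1
  .nearest_corr(r)
}

RUN_LABELS <- c("REST1_LR", "REST1_RL", "REST2_LR", "REST2_RL")

#' Generate per-run labeled multichannel time series
#'
#' Samples each subject's parcel channels as Gaussian time series whose
#' population correlation equals the subject's session-level target FC (plus
#' run-level Fisher-z jitter), and attaches white-matter/CSF/global reference
#' channels, six motion parameters, and a framewise-displacement trace. With
#' `clean = FALSE`, slow polynomial drifts, motion-coupled artifacts and a
#' shared physiological-like nuisance source are injected into the channels
#' (what the denoising pipelines are meant to remove); `clean = TRUE` emulates
#' component-cleaned input.
#'
#' @param cohort cohort data frame (its subjects, in order).
#' @param truth matching `ground_truth`.
#' @param run_label one of `"REST1_LR"`, `"REST1_RL"`, `"REST2_LR"`,
#'   `"REST2_RL"`.
#' @param n_timepoints volumes per run (reference acquisition: 1200).
#' @param tr_s repetition time in seconds (reference acquisition: 0.72).
#' @param clean if `TRUE`, no drift/motion/physiological artifacts are added.
#' @param drift_amplitude SD of the random polynomial drift (z-scored signal
#'   units).
#' @param motion_artifact_sd amplitude of the motion-coupled artifact.
#' @return list of `run_timeseries` objects, one per subject.
#' @export
generate_run_timeseries <- function(cohort, truth, run_label = RUN_LABELS,
                                    n_timepoints = 1200, tr_s = 0.72,
                                    clean = FALSE,
                                    drift_amplitude = 0.6,
                                    motion_artifact_sd = 0.4) {
  run_label <- match.arg(run_label)
  .assert(n_timepoints >= 8, "n_timepoints must be >= 8")
  .assert(tr_s > 0, "tr_s must be > 0")
  p <- truth$n_parcels
  .assert(p >= 2, "need at least 2 parcels")
  session <- sub("_(LR|RL)$", "", run_label)
  run_num <- match(run_label, RUN_LABELS)

  z_sess <- unclass(generate_session_edges(truth, session))
  set.seed((truth$seed %% 1000003L) * 4L + 100L + run_num)
  n <- nrow(cohort)
  tt <- seq(-1, 1, length.out = n_timepoints)

  lapply(seq_len(n), function(s) {
    zv <- z_sess[s, ] + stats::rnorm(truth$n_edges, sd = truth$run_noise_sd)
    r <- tanh(unvectorize(zv, p))
    diag(r) <- 1
    ch <- .chol_nearest_corr(r)
    parcels <- matrix(stats::rnorm(n_timepoints * p), n_timepoints) %*% ch

    # motion: slow random walk + occasional spikes (translations mm, rotations
    # rad); calibrated so FD sits near 0.07 mm with spike excursions > 0.25 mm
    motion <- matrix(0, n_timepoints, 6)
    for (k in 1:3) motion[, k] <- cumsum(stats::rnorm(n_timepoints, sd = 0.015))
    for (k in 4:6) motion[, k] <- cumsum(stats::rnorm(n_timepoints, sd = 3e-4))
    n_spk <- stats::rbinom(1, 3, 0.5)
    if (n_spk > 0) {
      at <- sample(2:n_timepoints, n_spk)
      motion[at, 1:3] <- motion[at, 1:3] +
        matrix(stats::rnorm(n_spk * 3, sd = 0.3), n_spk)
    }
    colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

    physio <- matrix(stats::rnorm(n_timepoints * 2), n_timepoints)  # shared WM/CSF sources
    wm <- physio %*% matrix(c(0.7, 0.2, 0.2, 0.7, 0.5, 0.5), 2, 3) +
      matrix(stats::rnorm(n_timepoints * 3, sd = 0.5), n_timepoints)
    csf <- physio %*% matrix(c(0.6, 0.3, 0.3, 0.6), 2, 2) +
      matrix(stats::rnorm(n_timepoints * 2, sd = 0.5), n_timepoints)

    if (!clean) {
      drift_basis <- cbind(tt, tt^2, tt^3)
      add_drift <- function(x) {
        x + drift_basis %*% matrix(stats::rnorm(3 * ncol(x), sd = drift_amplitude), 3)
      }
      parcels <- add_drift(parcels)
      wm <- add_drift(wm)
      csf <- add_drift(csf)
      mo <- scale(motion)
      parcels <- parcels + mo %*% matrix(stats::rnorm(6 * p, sd = motion_artifact_sd / sqrt(6)), 6)
      parcels <- parcels + physio %*% matrix(stats::rnorm(2 * p, sd = 0.2), 2)
    }
    global <- rowMeans(parcels) + stats::rnorm(n_timepoints, sd = 0.1)

    channels <- cbind(parcels, wm, csf, global)
    roles <- c(rep("parcel", p), rep("wm", 3), rep("csf", 2), "global")
    colnames(channels) <- make.unique(roles)

    fd <- framewise_displacement(motion)
    structure(list(subject_id = cohort$subject_id[s],
                   run_label = run_label,
                   tr_s = tr_s,
                   channels = channels,
                   roles = roles,
                   motion = motion,
                   fd = fd,
                   censor_mask = rep(TRUE, n_timepoints)),
              class = "run_timeseries")
  })
}

#' Framewise displacement from six realignment parameters
#'
#' Sum of absolute backward differences over the six parameters, with the
#' three rotations (radians) converted to millimetres of arc on a 50 mm
#' sphere. The first time point has FD 0.
#'
#' @param motion time x 6 matrix: three translations (mm), three rotations
#'   (radians).
#' @export
framewise_displacement <- function(motion) {
  .assert(is.matrix(motion) && ncol(motion) == 6, "motion must be time x 6")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * 50
  c(0, rowSums(d))
}

#' Generate NEO-FFI item responses from latent traits
#'
#' Each of a trait's 12 items is a noisy copy of the latent trait,
#' discretized into the five Likert levels by thresholding the Gaussian item
#' propensity at equal-probability cut points; reverse-keyed items are
#' emitted pre-reversal, so that [score_neoffi()] inverts the generator.
#'
#' @param cohort cohort data frame with `trait_O` .. `trait_N` columns.
#' @param model the [latent_trait_model()] (for `item_noise_sd`).
#' @param seed integer seed.
#' @return item response table (`subject_id`, `item_1` .. `item_60`).
#' @export
generate_item_responses <- function(cohort, model, seed = 1) {
  .assert(all(paste0("trait_", NEO_FACTORS) %in% names(cohort)),
          "cohort lacks latent trait columns")
  set.seed(seed)
  n <- nrow(cohort)
  noise <- model$item_noise_sd
  cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8), sd = sqrt(1 + noise^2))
  out <- matrix(NA_integer_, n, 60)
  for (f in NEO_FACTORS) {
    t_f <- cohort[[paste0("trait_", f)]]
    for (it in NEO_ITEM_MAP[[f]]) {
      prop <- t_f + stats::rnorm(n, sd = noise)
      coded <- findInterval(prop, cuts)        # 0..4
      out[, abs(it)] <- if (it < 0) 4L - coded else coded
    }
  }
  items <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  items[paste0("item_", 1:60)] <- as.data.frame(out)
  items
}

#' Apply the cohort inclusion criteria
#'
#' Filters, in order: (i) behavioral completeness, (ii) MMSE (a score of 26
#' or below excludes the subject), (iii) fMRI completeness, (iv) per-run head
#' motion (RMS frame-to-frame motion exceeding the threshold in any of the
#' four runs excludes the subject). Each excluded subject is logged with the
#' first criterion that removed them.
#'
#' @param cohort cohort data frame.
#' @param mmse_cutoff exclude when `mmse <= mmse_cutoff` (default 26).
#' @param motion_rms_max per-run RMS motion threshold in mm (default 0.15).
#' @return the filtered cohort; attribute `"exclusions"` holds a data frame
#'   of `subject_id` and `reason`.
#' @export
apply_inclusion_criteria <- function(cohort, mmse_cutoff = 26,
                                     motion_rms_max = 0.15) {
  required <- c("subject_id", "behavior_complete", "mmse", "fmri_complete",
                paste0("run_motion_rms_", 1:4))
  for (col in required) {
    .assert(col %in% names(cohort), "cohort is missing required column '%s'", col)
  }
  reason <- rep(NA_character_, nrow(cohort))
  flag <- function(cond, label) {
    reason[is.na(reason) & cond] <<- label
  }
  flag(!cohort$behavior_complete, "incomplete_behavioral")
  flag(cohort$mmse <= mmse_cutoff, "MMSE")
  flag(!cohort$fmri_complete, "incomplete_fmri")
  rms <- as.matrix(cohort[, paste0("run_motion_rms_", 1:4)])
  flag(apply(rms > motion_rms_max, 1, any), "motion")
  keep <- is.na(reason)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    subject_id = cohort$subject_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}
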