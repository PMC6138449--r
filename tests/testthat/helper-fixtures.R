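# Shared fixtures, all built in code.

# cohort spec with every FC-trait and FC-confound path switched off:
# the connectome then carries no information about any score
null_signal_spec <- function(n_subjects, n_parcels = 60, seed = 1, ...) {
  ce <- default_confound_effects()
  for (nm in names(ce)) ce[[nm]]$edge_r <- 0
  cohort_spec(n_subjects = n_subjects, n_parcels = n_parcels, seed = seed,
              trait_model = latent_trait_model(signal_effect = 0),
              confound_effects = ce, ...)
}

# spec with a planted signal on the Openness trait only and no confound->FC paths
planted_spec <- function(n_subjects, effect, n_signal_edges = 100,
                         n_parcels = 60, seed = 1, ...) {
  ce <- default_confound_effects()
  for (nm in names(ce)) ce[[nm]]$edge_r <- 0
  cohort_spec(n_subjects = n_subjects, n_parcels = n_parcels, seed = seed,
              trait_model = latent_trait_model(
                signal_effect = c(effect, 0, 0, 0, 0),
                signal_edges_per_trait = n_signal_edges),
              confound_effects = ce, ...)
}

# minimal synthetic run: given parcel channels (and optional extras), wrap as
# a run_timeseries with quiet motion
make_run <- function(parcels, wm = NULL, csf = NULL, global = NULL,
                     tr_s = 0.72, fd = NULL, motion = NULL,
                     subject_id = "S0001", run_label = "REST1_LR") {
  n_time <- nrow(parcels)
  if (is.null(wm)) wm <- matrix(rnorm(n_time * 3), n_time)
  if (is.null(csf)) csf <- matrix(rnorm(n_time * 2), n_time)
  if (is.null(global)) global <- rowMeans(parcels)
  if (is.null(motion)) motion <- matrix(rnorm(n_time * 6, sd = 1e-4), n_time)
  if (is.null(fd)) fd <- framewise_displacement(motion)
  channels <- cbind(parcels, wm, csf, global)
  roles <- c(rep("parcel", ncol(parcels)), rep("wm", ncol(wm)),
             rep("csf", ncol(csf)), "global")
  colnames(channels) <- make.unique(roles)
  structure(list(subject_id = subject_id, run_label = run_label, tr_s = tr_s,
                 channels = channels, roles = roles, motion = motion,
                 fd = fd, censor_mask = rep(TRUE, n_time)),
            class = "run_timeseries")
}

# item table where every subject answers every item with `value`
uniform_items <- function(value, n = 3) {
  items <- data.frame(subject_id = sprintf("S%02d", seq_len(n)))
  items[paste0("item_", 1:60)] <- value
  items
}

cv_r <- function(res) cor(res$observed, res$predicted)
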