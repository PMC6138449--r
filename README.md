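# connpred

Connectome-based prediction of personality and cognition from resting-state
functional connectivity, as a tested, reusable R pipeline.

## The problem

Resting-state fMRI studies increasingly try to predict stable individual
traits — the Big Five personality factors, fluid intelligence — from the
functional connectome: the matrix of pairwise Pearson correlations between
the BOLD time series of brain parcels. Doing this credibly requires a chain
of non-trivial methodological safeguards, each of which this package
implements and tests:

* **NEO-FFI scoring.** Sixty 5-point Likert items (0–4) are summed into the
  O/C/E/A/N factor scores after reverse-coding the keyed items (reversed
  value = 4 − raw); internal consistency via Cronbach's α; two orthogonal
  superordinate components (α, β) from a correlation-matrix PCA of the five
  factor scores.
* **Denoising.** Three published nuisance-regression pipelines (A: z-score →
  Legendre-3 CSF/WM detrend → tissue-mean regression → 12-parameter motion
  regression → Gaussian low-pass (SD = 1 TR) → Legendre-3 detrend → global
  signal regression; B: demean → quadratic detrend → 0.01–0.08 Hz zero-phase
  Butterworth band-pass with interpolation over censored volumes → one
  combined regression of expanded tissue/motion/global terms plus spike
  regressors; C, for component-cleaned input: demean → linear detrend →
  CompCor + GM + whole-brain regression with FD/DVARS censoring → band-pass).
* **Connectomes.** Parcelwise Pearson FC per run, Fisher z-transform, run and
  session averaging in z-space, and row-major upper-triangle vectorization
  into subjects × edges matrices (`n_edges(p) = p(p−1)/2`; 35,778 edges for a
  268-node parcellation).
* **Test–retest reliability.** Connectome fingerprinting (identification
  success rate), reproducibility of the between-subject similarity matrix,
  and reproducibility of the edgewise trait-correlation ("behavioral
  utility") map across sessions.
* **Prediction with leakage control.** Confounds (sex, age, handedness,
  fluid intelligence, brain size, motion, reconstruction version) are
  regressed out of the score with coefficients fitted on the training fold
  only; cross-validation leaves out whole families so kinship cannot leak;
  models are the univariate network-strength regressions on positively /
  negatively filtered edges (per-edge p < .01 filter) and an elastic net
  (L1 ratio 0.01, 50-value penalty grid, quartile-stratified 3-fold nested
  selection) on the union of filtered edges.
* **Honest evaluation.** Pearson r between observed and predicted scores,
  the cross-validated coefficient of determination
  R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² (which can be negative and must not be replaced
  by r²), RMSD, nRMSD = RMSD/SD(y), and family-preserving permutation tests
  with the (k+1)/(n+1) empirical p rule.

Because the reference data (Human Connectome Project) are access-restricted,
the package ships a first-class synthetic cohort generator with known ground
truth — family structure, trait intercorrelations, confound→trait and
confound→edge paths, subject-stable connectome fingerprints with a
family-shared share, and planted trait-linked edges — so every stage is
testable end to end, including parameter recovery and type-I calibration.

## Worked example

```r
library(connpred)

spec <- cohort_spec(n_subjects = 100, n_parcels = 60, seed = 1,
                    trait_model = latent_trait_model(
                      signal_effect = c(0.5, 0, 0, 0, 0)))
sim    <- generate_cohort(spec)
items  <- generate_item_responses(sim$cohort, spec$trait_model, seed = 1)
traits <- score_neoffi(items)

runs <- generate_run_timeseries(sim$cohort, sim$truth, "REST1_LR",
                                n_timepoints = 300)
fc   <- lapply(runs, function(r) fc_matrix(denoise(r, denoise_config("A"))))
X    <- stack_subjects(fc, sim$cohort$subject_id, session = "REST1")

cfg <- model_config("univariate_pos", deconfound_set = "full", target = "O")
res <- predict_cv(X, traits$O, sim$cohort, sim$cohort$family_id, cfg)
ev  <- evaluate_predictions(res$observed, res$predicted)
round(unlist(ev[c("r", "r2", "nrmsd")]), 3)
#>     r    r2 nrmsd
#> 0.616 0.378 0.789

permutation_test(X, traits$O, sim$cohort, sim$cohort$family_id, cfg,
                 n_perm = 99, seed = 1)$p
#> [1] 0.01
```

The printed numbers say: across the 100 subjects, each predicted exactly once
by a model that never saw their family, predicted and observed (deconfounded)
Openness scores correlate at r = 0.62; the model explains 38% of the variance
(R², not r²); the average prediction error is 0.79 of the observed-score SD
(a zero-information model gives R² ≈ 0 and nRMSD ≈ 1; this synthetic cohort
plants a much stronger trait signal than real cohorts show). The permutation
p comes from rerunning exactly this pipeline on shuffled scores while keeping
the family folds fixed: no shuffled replicate beat the observed r.

Reliability metrics work on two sessions of edge matrices:

```r
s1 <- generate_session_edges(sim$truth, "REST1")
s2 <- generate_session_edges(sim$truth, "REST2")
identification_success_rate(s1, s2)$isr   # 100 (percent) at these settings
similarity_testretest(s1, s2)             # 0.59
```

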