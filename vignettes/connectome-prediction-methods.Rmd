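---
title: "Methods: connectome-based trait prediction with leakage control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based trait prediction with leakage control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, the parameters that matter, and the
design decisions taken where the methodology left genuine choices open.

## The prediction problem

The package predicts a stable psychological score (a Big Five factor, a
superordinate personality component, or fluid intelligence) from a subject's
resting-state functional connectome: the vector of Fisher-z-transformed
Pearson correlations between all pairs of brain-parcel time series. The
statistical obstacles are (i) dimensionality — tens of thousands of edges
against hundreds of subjects; (ii) confounding — sex, age, head motion, brain
size, scanner reconstruction version and fluid intelligence all correlate
with both traits and connectivity; (iii) kinship — cohorts contain families,
and relatives share both traits and connectomes, so naive cross-validation
leaks; and (iv) evaluation — the Pearson correlation between observed and
predicted scores cannot be squared into an estimate of explained variance in
a cross-validated setting.

## Trait measurement

`score_neoffi()` codes each 60-item NEO-FFI response as 0–4 (strongly
disagree to strongly agree), reverses the keyed items as `4 - x`, and sums
the 12 items of each factor into O/C/E/A/N scores on 0–48. Item 59 is
reverse-keyed within Agreeableness (an early release of the reference
database had failed to reverse it; this implementation reverses it).
`cronbach_alpha()` uses the classical `k/(k-1) * (1 - sum(var_i)/var_total)`
form on reverse-corrected items with n−1 variances.

`superordinate_pca()` computes the two leading principal components of the
five factor scores. The PCA is run on the **correlation** matrix
(standardized factors): the factors share a 0–48 scale but differ in
variance, and loadings are interpreted comparably across factors. Whether
the reference analysis standardized is not documented; correlation-PCA is
this package's decision, and the variance-explained figures it reports should
be read under that convention. Components are oriented so the
largest-|loading| factor loads positively, and scores are scaled to unit
variance; orthogonality is exact by construction.

## Denoising pipelines

Each `run_timeseries` carries parcel channels, white-matter/CSF reference
channels, a global (whole-brain) channel, six realignment parameters, and a
framewise-displacement (FD) trace. `denoise()` composes labeled operators in
the published order of one of three pipelines:

* **A** — z-score each channel; third-degree Legendre detrend of CSF/WM;
  regression of the CSF and WM means from parcels; regression of the 6 motion
  parameters and their backward-difference derivatives (12 columns); Gaussian
  low-pass with kernel SD one TR (0.72 s), truncated at ±4 SD with reflect
  padding; third-degree Legendre detrend of parcels; global-signal
  regression.
* **B** — demean; linear+quadratic detrend; zero-phase first-order
  Butterworth band-pass 0.01–0.08 Hz after linear interpolation over volumes
  marked for censoring (FD > 0.25 mm); then a single combined regression of
  CSF/WM/global signals with derivatives and quadratic terms, the 24-column
  motion expansion, and one spike regressor per censored volume. Censoring
  is absorbed by the spike regressors, so all volumes remain available
  downstream.
* **C** — intended for component-cleaned (FIX-like) input: demean; linear
  detrend; regression of 5 CompCor components (principal components of the
  pooled standardized WM/CSF channels) plus the gray-matter and whole-brain
  means, with coefficients estimated on retained volumes only; band-pass
  with interpolation. Volumes censored by FD > 0.25 mm or DVARS > 1.05× the
  run median stay flagged and are excluded from FC computation.

Numerical choices: filtering is zero-phase (forward–backward), so the
amplitude response is the squared single-pass response — phase distortion
would bias correlations. Nuisance regressions always include an intercept
and drop collinear columns by QR pivoting with a warning. Pipeline B's
nuisance columns are filtered exactly like the data before the combined
regression (whether the reference did so is unstated). Pipeline A's
published order applies its temporal filter before the final regressions,
which can reintroduce high-frequency content; the order is reproduced as
printed, not "fixed". An execution trace is attached to every denoised run
and asserted in tests.

Two parcel-resolution caveats. First, operators act on parcel and tissue
*channels*, not voxels; every step commutes with within-parcel averaging
except tissue-mean extraction, which the generator supplies directly.
Second, DVARS computed across only ~60 parcels is much noisier than across
thousands of voxels, so pipeline C's 1.05×-median rule censors a visible
fraction (tens of percent) of frames on synthetic runs; this is a property
of the printed rule at parcel resolution, not of the implementation.

## Connectomes

`fc_matrix()` correlates parcel channels over retained volumes, caps |r| at
1 − 1e−7 before `atanh` (the cap is this package's guard; the reference does
not state one), and zeroes the diagonal. All averaging — runs into sessions,
sessions into REST12 — is element-wise in z-space, and edge values stay in
z units for every downstream model, which is immaterial for the
scale-equivariant linear models used. The upper triangle is vectorized in
row-major (i < j) order; any fixed order works if used everywhere, and this
one is asserted by round-trip tests.

## Prediction with leakage control

`predict_cv()` runs leave-one-family-out (LOFO) cross-validation: one fold
per family, the whole family held out. Within each fold, in order: (1) the
confound regression (full set: gender, age, handedness, fluid intelligence,
brain size, per-session motion sums, reconstruction version; minimal set:
reconstruction version, motion, brain size; the target score is never in its
own confound set) is fitted on the training subjects only and its
coefficients applied to both training and held-out scores; (2) edges are
filtered by the two-sided p < .01 of their training-fold Pearson correlation
with the deconfounded score, split by sign; (3) the configured model is
fitted on the training fold and evaluated on the family. The univariate
model regresses the score on the network strength (the sum of masked edge
values); an empty mask falls back to the training mean, logged. The
multivariate model is an elastic net with L1 ratio 0.01 (nearly ridge) on
the union of the positive and negative masks, features standardized by
training mean/SD, penalty chosen from 50 geometrically spaced values spanning
[1e−4, 1]×α_max (α_max zeroes all coefficients) by 3-fold inner
cross-validation stratified over quartile bins of the training score, ties
to the larger penalty, then refitted on the whole training fold. The grid's
span and spacing, and the deterministic rank-round-robin fold assignment
within quartile bins, are this package's choices (unreported in the
reference) and are recorded in every result.

The fold loop computes each fold's edgewise training correlations by
downdating cohort-level sufficient statistics (column sums, squared sums,
and cross-products with the score and the confound design) by the held-out
family's rows — algebraically identical to recomputing on the training
submatrix, and asserted equal in tests — which makes the permutation test's
thousands of pipeline reruns affordable.

Observed scores are recorded as the fold-specific deconfounded values (the
train-only regression applied to the held-out family), matching the
train-only contract; a global-residual variant can be had by deconfounding
before calling `predict_cv()` with `deconfound_set = "none"`.

## Evaluation and inference

`evaluate_predictions()` reports r, the cross-validated
R² = 1 − SS_res/SS_tot (negative when the model does worse than the mean),
RMSD and nRMSD = RMSD/SD(obs). Two denominator conventions are offered:
the population convention (1/n; makes nRMSD² + R² = 1 an exact identity) and
the residual convention (n−2 for RMSD, as the standard deviation of
residuals about a fitted line, n−1 for SD(obs)), under which published
(r, R², nRMSD) triplets at large n are internally consistent —
`nrmsd_from_r2(r2, n)` exposes the mapping
`sqrt((1 - r2) * (n - 1) / (n - 2))`, reducing to `sqrt(1 - r2)` at
`n = Inf`.

`permutation_test()` shuffles the raw scores between subjects, keeps
everything else fixed — confounds, edges, and the family-based folds — and
reruns the entire deconfound→filter→fit→evaluate chain per replicate;
p = (1 + #{replicate ≥ observed})/(n_perm + 1), valid under exchangeability.
Permuted scores are deconfounded against the unpermuted confounds (the
literal reading of keeping everything else the same). Parametric correlation
thresholds are inappropriate here because folds are dependent; the test
suite checks that the empirical null band is wider than the parametric one
and that the univariate model's null is left-skewed relative to the elastic
net's.

## Test–retest reliability

Three metrics compare sessions: the identification success rate (a subject
is identified when their session-1 edge vector correlates most highly with
their own session-2 vector among all subjects; ties go to the lowest roster
index with a warning; both directions reported), the correlation between the
two sessions' subject-pairwise similarity matrices (upper triangles only —
the unit diagonal would inflate it), and the correlation between the two
sessions' edgewise trait-correlation maps (behavioral utility; deconfounded
scores are the intended input).

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws families (default size distribution averaging ~2.2
members, matching the reference cohort's subjects-per-family ratio), latent
Big Five traits as family + individual multivariate normal components
(default sibling correlation 0.5; default intercorrelation matrix shaped
like published NEO-FFI samples: Neuroticism anticorrelated with C/E/A, those
three positively intercorrelated, Openness nearly separate), confounds
correlated with traits, inclusion-relevant fields (MMSE, completeness flags,
per-run motion RMS calibrated so roughly a tenth of subjects exceed the
0.15 mm exclusion threshold), and a connectome ground truth in Fisher-z
space: per edge, a group mean plus a standardized mixture of family-shared,
subject-stable and session-noise components governed by `fingerprint_share`
(fraction of non-group edge variance stable across sessions, default 0.5)
and `familial_fc_share` (fraction of the stable part shared within family,
default 0.3). Planted trait edges replace that mixture by
`effect * trait + sqrt(1 - effect^2) * mixture`, so the edge–trait
correlation equals `effect` by construction; confound→edge paths are built
the same way. Item responses are Gaussian propensities (latent trait plus
item noise) discretized at equal-probability cut points and emitted
pre-reversal, so scoring inverts the generator exactly in the noiseless
limit. The default item noise SD of 1.5 comes from the Spearman–Brown
algebra for 12 parallel items after 5-level discretization and places
Cronbach's α near 0.8, the reliability regime reported for the instrument.

Run time series are sampled as Gaussian vectors whose population correlation
is the subject's session target FC: `tanh` of the session edge vector,
projected to the nearest valid correlation matrix (eigenvalues clipped at
1e−4, diagonal renormalized). The projection is necessary because per-edge
targets are generated freely and need not form a positive-semidefinite
matrix; `target_fc()` exposes the projected matrix, which is what empirical
FC provably converges to. Raw (non-FIX-like) runs add slow random polynomial
drifts, a motion-coupled artifact built from the simulated realignment
parameters (random walk plus occasional spikes, calibrated to a median FD
near 0.07 mm), and a shared WM/CSF "physiological" source that also leaks
into parcels — the structures the three pipelines are designed to remove. FD
is the sum of absolute backward differences of the six parameters with
rotations converted to millimetres on a 50 mm sphere (the standard
convention; the reference does not define its computation).

What the generator does **not** emulate: voxel-level structure and spatial
autocorrelation, physiological rhythms with realistic spectra, non-Gaussian
BOLD marginals, distance-dependent motion artifacts, trait drift between
sessions (traits are exactly stable), and measurement of tissue signals by
segmentation (tissue channels are supplied directly). Passing tests
therefore certify the statistical machinery — calibration, leakage control,
recovery, reliability metrics — not performance on real acquisitions.

## Problem sizes used by the test suite

The statistical acceptance checks run at sizes chosen to keep the full suite
in the minutes range while leaving each check adequately powered: edge-filter
calibration on 50 null datasets of 200 subjects × 10,000 edges; permutation
type-I uniformity on 50 zero-signal cohorts of 100 subjects × 60 parcels with
200 permutations each; recovery on 400-subject cohorts with 100 planted
edges at effects 0.1/0.3/0.5 (39 permutations for significance); the
family-leakage demonstration on 60 two-sibling families over 10 seeds; the
null-shape comparison with 300 permutations per model. The fingerprint dial
is checked on a 20-parcel connectome, where identification is off its 100%
ceiling and the share parameter is resolvable.

## Known limitations

Pipeline C is not ICA-FIX — it consumes input that is already
component-cleaned (the generator's `clean = TRUE` mode). No facet-level NEO
scoring, no partial correlations or tangent-space connectomes, no nonlinear
prediction models, no multiple-comparison correction across analysis-grid
cells, and no imaging-format ingestion (plain TSV/JSON interchange only; a
`parcellate` seam for real label maps is out of scope). The elastic-net
penalty grid and standardization conventions are reasonable but not
reference-verified; both are logged in every result so sensitivity analyses
are one loop away.
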