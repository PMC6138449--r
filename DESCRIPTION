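Package: connpred
Title: Connectome-Based Prediction of Personality from Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectome-based predictive modeling of stable
    psychological traits from resting-state fMRI functional connectivity.
    Implements NEO-FFI Big Five scoring with superordinate principal
    components, three published nuisance-regression denoising pipelines for
    parcellated BOLD time series, Fisher-z functional connectome construction,
    test-retest reliability metrics (connectome fingerprinting identification
    success rate, pairwise-similarity and behavioral-utility reproducibility),
    train-only deconfounding, leave-one-family-out cross-validated univariate
    (network-strength) and elastic-net prediction, cross-validated R-squared /
    nRMSD evaluation, and family-preserving permutation inference. A synthetic
    cohort generator with known ground truth (family structure, subject-stable
    connectivity fingerprints, confound effects, planted trait-linked edges)
    supports end-to-end validation without access to restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
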