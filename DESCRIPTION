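Package: gmmvoice
Title: Speech Biomarkers for Movement Disorders via GMM-UBM Supervectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Acoustic analysis of dysarthric speech for discriminating
    Parkinson's disease, essential tremor, and healthy controls. Extracts
    articulation (Bark-band energies and MFCCs at voicing onsets), phonation
    (jitter, shimmer, perturbation quotients), and prosody (F0 and energy
    contour models) features; fits diagonal-covariance Gaussian mixture
    universal background models by expectation maximization; adapts them to
    individual recordings by maximum a posteriori estimation with a relevance
    factor; stacks the adapted parameters into supervectors; and classifies
    them with radial-kernel support vector machines under repeated stratified
    cross-validation with nested hyperparameter search. Includes a synthetic
    speech generator emulating hypokinetic and hyperkinetic voice profiles
    for end-to-end evaluation without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    e1071,
    MASS,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
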