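Package: intervalnet
Title: Neural-Network Prediction Intervals for Pain-Intensity Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Construction and evaluation of neural-network prediction
    intervals for continuous pain-intensity estimation from physiological
    signal features. Implements a two-output feed-forward interval network
    trained either with a soft coverage-width loss (sigmoid-softened
    coverage, captured-only width, quadratic coverage-shortfall penalty)
    by minibatch Adam gradient descent, or with the lower-upper-bound
    estimation (LUBE) loss by a genetic algorithm, alongside a bootstrap
    ensemble baseline with epistemic/aleatoric variance decomposition.
    Provides prediction-interval quality metrics (PICP, MPIW, NMPIW and
    their soft counterparts), min-max preprocessing and stratified
    cross-validation, subject-level k-means clustering, the generalized /
    personalized / cluster-hybrid model-building regimes, hyperparameter
    search over published parameter spaces, and a synthetic cohort
    generator emulating the statistical structure of
    electrodermal-activity feature tables with known-quantile regression
    benchmarks for coverage validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
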