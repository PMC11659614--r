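Package: intflex
Title: Intrinsic Neural Timescales Across Behavioral States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of intrinsic neural timescales (tau from an
    exponential fit to the autocorrelation function, and ACW-0) in
    non-overlapping windows of multichannel neural recordings;
    segmentation of wheel-velocity traces into labeled behavioral
    states; rest-task statistics (percent change, variability-change
    correlations, Wilcoxon effect sizes, MAD outlier screening, Holm
    correction, Clogg coefficient comparison); nested cross-validated
    classification of behavioral states from whole-brain timescale
    features; and a connectome-coupled firing-rate model with a
    sigmoid transfer function, a firing-rate clamping controller,
    recurrent-connection sweeps, edge shuffling and Lyapunov spectra.
    Includes generators for state-dependent Ornstein-Uhlenbeck
    recordings, bout-structured wheel velocity, and synthetic
    connectomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    glmnet,
    pROC,
    pracma,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'acf.R'
    'classify.R'
    'intflex-package.R'
    'io.R'
    'lyapunov.R'
    'model.R'
    'pipeline.R'
    'segmentation.R'
    'stats.R'
    'sweep.R'
    'synthetic.R'
    'utils.R'
    'windows.R'
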