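Package: spectraTransfer
Title: Calibration Transfer for Vis-NIR Spectral Regression via Deep
    Feature Extraction and Boosting Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts a scalar reference property (wood air-dry density,
    g/cm3) from visible/near-infrared absorbance spectra measured under
    shifted acquisition conditions (moisture content). Implements a
    transfer-learning stack: a 1D residual convolutional network trained
    on the source condition, layer-frozen fine-tuning on the target
    condition, flatten-layer bottleneck features fed to an RBF support
    vector regressor tuned by particle swarm optimisation, and a
    two-stage instance-weighted boosting transfer (TrAdaBoost.R2 for
    regression) that re-weights source samples by binary search and
    boosts target samples. Also provides the standard chemometric
    toolbox the stack is compared against: Savitzky-Golay smoothing,
    standard normal variate correction, synchronous two-dimensional
    correlation diagnostics, a leverage/studentized-residual outlier
    screen, SPXY calibration-set selection, PLS1 regression, slope/bias
    correction and piecewise direct standardization, plus a generator of
    domain-shifted synthetic spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
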