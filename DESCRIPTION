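Package: nirauth
Title: NIR Spectral Authentication and Adulteration Quantification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for near-infrared (NIR) authentication of
    powdered botanical materials, built around the adulteration problem of
    Dendrobium officinale (DKM). Provides a calibrated synthetic NIR spectrum
    generator (pure classes, binary mixtures, scatter/baseline/noise, batch
    effects), spectral preprocessing (SNV, MSC, Savitzky-Golay smoothing and
    derivatives) with a registry of named pipelines, Kennard-Stone sample
    selection and split schemes, PCA/PLS-DA/OPLS-DA exploration, a data-driven
    SIMCA (DD-SIMCA) one-class classifier with chi-squared acceptance regions,
    PLS1 regression of adulterant mass fraction with latent-variable selection
    by cross-validation and a preprocessing screening harness, and a battery of
    supervised baselines (decision tree, linear SVM, neural network, naive
    Bayes) with stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
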