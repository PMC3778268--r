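Package: lesionprog
Title: Lesion-Based Prognosis of Speech Production After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts 3-D tissue-abnormality images from stroke patients into
    binary lesion masks and atlas-based regional damage features, combines
    them with demographics and time post-stroke, and fits Gaussian process
    regression with a rational-quadratic automatic-relevance-determination
    (ARD) covariance to predict a composite speech-production T-score.
    Provides leave-one-out cross-sectional and longitudinal validation,
    ARD-driven predictor subset selection, ROC analysis, paired Wilcoxon
    error comparisons, and per-patient probabilistic recovery prognoses over
    months post-stroke. A synthetic-cohort generator with a known
    structure-function-time model supports end-to-end testing without any
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
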