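Package: ghoutliers
Title: Shape-Aware Univariate Outlier Removal with Tukey g-and-h Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects and removes univariate outliers from tabular numeric
    data by classifying each feature's distribution shape (multimodal,
    monotonic, or unimodal two-sided), applying an asymmetrical-outlyingness
    probit transform, fitting Tukey g-and-h models by percentile regression
    (including a bimodal mixture fitted by stochastic EM), and flagging
    points outside the fitted model's central 99.3% coverage region.
    Includes Hartigan's dip test with a bootstrap null drawn from the
    closest unimodal distribution, simulation generators for benchmark
    distributions and outlier-injection schemes, classical baseline
    detectors (IQR, MAD, 3SD, iterative refitting, Yeo-Johnson variants,
    two-percentile g-and-h estimation), and ground-truth evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    car,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
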