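Package: cvdscreen
Title: Screening Scientific Figures for Deuteranopia Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Flags raster figures (PNG/JPEG) that are likely to be hard to
    interpret for people with deuteranopia, the most common red-green color
    vision deficiency. Images are simulated under a severity-parameterized
    deuteranomaly matrix, compared with the original via the CIEDE2000 color
    difference, and summarized with five quantitative accessibility metrics
    plus a corpus-level rank-based combined score. Includes feature-based
    classifier training and evaluation (logistic regression, random forest,
    k-nearest neighbors) under repeated stratified cross-validation with
    AUROC/AUPRC scoring, a small configurable convolutional-network training
    harness, a deterministic synthetic-fixture generator with certified
    chromatic structure, and a command-line interface for batch screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jpeg,
    randomForest,
    class,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    colorspace,
    farver,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
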