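Package: mirtoo
Title: MicroRNA-Based Tissue-of-Origin Prediction for Cancers of Unknown Primary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the tissue of origin of metastatic cancers of
    unknown primary from droplet digital PCR absolute quantification of a
    focused microRNA panel. Implements panel quality-control and cDNA dilution
    rules, 50th-percentile normalization and panel filtering, two per-class
    probability classifiers (nearest shrunken centroids and L1-penalized
    multinomial regression fitted by coordinate descent), sex-compatibility
    filtering with a two-criterion call prioritization rule, bootstrap
    out-of-bag error assessment, and per-miRNA survival screening with
    ROC-optimal dichotomization, Kaplan-Meier/log-rank tests, and univariate
    Cox hazard ratios. A synthetic ddPCR cohort generator with class-specific
    log-normal expression profiles, liver-microenvironment miR-122-5p
    inflation, and expression-driven survival provides fully reproducible test
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    glmnet,
    withr
Config/testthat/edition: 3
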