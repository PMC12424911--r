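Package: painnet
Title: Partial-Correlation Network Analysis of Chronic Pain Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for estimating regularized partial-correlation
    networks (Gaussian graphical models) from questionnaire data on chronic
    pain. Covers participant-level data cleaning, psychometric scoring with
    reverse coding and person-mean imputation, normality diagnostics
    (marginal skewness, Henze-Zirkler test), the rank-based nonparanormal
    transformation, nodewise LASSO estimation with 10-fold cross-validation
    and Loh-Wainwright style thresholding, node predictability, nonparametric
    bootstrap edge stability, and a network-recovery simulation study for
    sample-size planning. A synthetic-data module generates ground-truth
    sparse Gaussian graphical models and Likert-style survey datasets so the
    whole pipeline is testable without access to the original study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    yaml,
    e1071,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
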