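Package: hazardbn
Title: Data-Driven Hazard Criteria for Silver Nanoforms via Constrained
    Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline deriving quantitative intrinsic hazard
    criteria for silver nanoforms from physicochemical and in-vitro
    cytotoxicity data.  Covers strata-wise dose interpolation, iterative
    chained imputation with gradient-boosted trees, SMOTE class balancing,
    tercile quantile discretization, mixed-type association analysis
    (Spearman's rho, Cramer's V) with a Mapper topological summary, QSAR
    baseline models, expert-constrained discrete Bayesian-network structure
    learning (exact dynamic programming and hill climbing) with smoothed
    conditional probability tables and exact posterior inference, and the
    mining of those tables into IF-THEN hazard rules carrying certainty
    factors.  A synthetic-data generator reproduces the statistical
    structure of the study design so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    xgboost,
    ranger,
    randomForest,
    rpart,
    rlang,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
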