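Package: sccapipe
Title: Sparse Canonical Correlation Pipelines for Multi-Site Two-Block Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a block of continuous morphometric (brain-structure) features
    to a block of mixed demographic, behavioural and environmental features with
    sparse canonical correlation analysis (penalized matrix decomposition with
    L1/L2 constraints). Covers the full analysis path used in multi-site
    adolescent neuroimaging cohorts: random-forest imputation of non-imaging
    variables, Mahalanobis multivariate outlier exclusion, empirical-Bayes
    (ComBat) site harmonization, standardization, longitudinal change-score
    residualization, sparsity tuning on a 1/sqrt(p)-to-1 grid, exact permutation
    P values, FDR gating, and a resampling robustness battery
    (redundancy-reliability scores, stability curves, split-half
    generalization, quality-score association). Ships a synthetic two-block
    cohort generator with known sparse canonical structure for parameter
    recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    MASS,
    sva
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
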