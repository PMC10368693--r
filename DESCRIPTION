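Package: miRatio
Title: Normalization-Free Circulating miRNA Ratio Biomarker Discovery and
    Cross-Platform Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of circulating microRNA ratio
    biomarkers for nested case-control screening studies. Builds all
    pairwise within-sample ratios from small-RNA sequencing raw counts
    (so per-sample scaling cancels and no normalizer is needed), screens
    them with a dual fold-change / control-coefficient-of-variation
    strategy on Mann-Whitney tests with Benjamini-Hochberg correction,
    selects a signature by L1-penalised logistic regression, and assesses
    models by stratified cross-validation with calibration intercept and
    slope, scaled Brier score and AUC, DeLong ROC comparisons and the
    Youden cut-off. Includes RT-qPCR triplicate Ct quality control and
    delta-Ct ratio computation for cross-platform concordance, a
    SNP-dosage polygenic risk score, and a synthetic cohort generator
    emulating the statistical structure of all inputs so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
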