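Package: ERSScore
Title: Endoplasmic Reticulum Stress Signature Scoring and Case-Control
    Genetics for Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates a principal-component based endoplasmic
    reticulum stress score (ERSS) for tumor cohorts: differential
    expression and gene-set enrichment, univariate Cox screening with
    sign-split gene clusters, the PC1-difference score, maximally
    selected rank-statistic cutpoints, Kaplan-Meier/log-rank/Cox
    survival analysis, time-dependent ROC, single-sample GSEA and
    ESTIMATE-style immune scores, tumor mutational burden, a
    nomogram-equivalent risk model with calibration and decision
    curves, and WGCNA-style co-expression modules. A companion
    case-control arm covers Hardy-Weinberg testing, odds ratios,
    logistic adjustment, crossover analysis and additive
    (RERI/AP/S) and multiplicative interaction. Synthetic cohort
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
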