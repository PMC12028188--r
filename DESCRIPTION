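Package: afprank
Title: Multi-Model Ranking of Follow-Up Biomarkers for Alpha-Fetoprotein
    Alteration in Tyrosinemia Type 1
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ranking routine follow-up laboratory variables by
    their ability to predict alpha-fetoprotein (AFP) alteration in
    hereditary tyrosinemia type 1 (HT-1) cohorts. Implements a synthetic
    longitudinal cohort generator, record filtering and chained-equations
    imputation, a univariate association screen (Spearman, Kruskal-Wallis
    with Dunn post hoc, Anderson-Darling), a bootstrapped multi-model
    gradient-boosted-tree ensemble with TreeSHAP explanations and
    performance-corrected importance, cross-cohort consensus clustering,
    leave-one-variable-out logistic ablation, and ROC-derived biomarker
    cut-offs with bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    glmnet,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
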