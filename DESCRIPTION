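Package: presaboost
Title: Presence/Absence Degradation Analysis of Microbiome Taxonomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the host-phenotype classification signal in
    microbial relative-abundance profiles survives degradation to presence/absence.
    Reads and validates MetaPhlAn-style merged abundance tables and 16S OTU count
    tables, aggregates species profiles to coarser taxonomic ranks, binarizes
    profiles at configurable detection thresholds, evaluates random-forest,
    lasso, elastic-net and SVM classifiers under repeated stratified
    cross-validation and leave-one-dataset-out transfer, compares paired fold-level
    AUCs with a repeated-CV confidence interval and t-test, and contrasts
    differential-abundance (Mann-Whitney U) with differential-presence (Fisher
    exact) testing under FDR control. A seeded generator of sparse compositional
    case/control cohorts with prevalence-shift and abundance-shift biomarkers,
    multinomial read-sampling detection limits and multi-study batch structure
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
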