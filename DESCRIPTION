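Package: rankRF
Title: Rank-Based Random Forest Analysis of Cross-Platform Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating heterogeneous gene-expression cohorts by
    within-sample ranking and analysing them with Random Forest classifiers.
    Implements consensus Boruta shadow-feature gene selection with an exact
    binomial acceptance test, rank-forest fitting and evaluation for binary
    and multi-class phenotypes, minimal-panel search by sequential floating
    forward selection, exact per-sample per-class Shapley attribution for
    tree ensembles, Mann-Whitney/Benjamini-Hochberg differential expression
    with a one-way ANOVA subtype stage, hypergeometric over-representation
    analysis, and a multi-platform synthetic cohort generator with planted
    class-informative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
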