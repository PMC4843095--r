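Package: rootheat
Title: Heat-Stress Root Omics: Poisson Mixed-Model Differential
    Expression, Regulatory Module Networks, and iTRAQ Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a heat-stress
    root omics analysis pipeline for paired root-hair and stripped-root
    samples. Provides per-gene Poisson log-linear mixed-model
    differential-expression testing with likelihood-ratio tests and
    Storey q-values, decision-tree gene-regulatory-module inference over
    discretized transcription-factor states, iTRAQ 8-plex reporter-ion
    peptide-to-protein quantification with pooled-reference and
    central-tendency normalization and Rrollup aggregation, and
    cross-omics integration utilities (directional overlap partitions,
    mRNA-protein correlation, qPCR fold changes, term enrichment).
    Every stage is exercised on synthetic data with planted ground truth
    generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tibble,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
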