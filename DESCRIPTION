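Package: erythrotune
Title: Feedback-Control Modeling and Statistics for Cytokine-Tuned Erythropoiesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how accessory cytokines such as IL-17A tune the
    erythropoietin (Epo)-mediated negative feedback loop that controls red blood
    cell production. Implements a four-compartment dynamical model of the
    erythroid feedback circuit with hypoxic-onset perturbations, response-speed
    (root integral-time-squared error) and over-production cost metrics,
    one-at-a-time parameter scans, random-ensemble Pareto-front analysis, and
    multiplicative-synergy experiments; Hill dose-response fitting and paired
    nonparametric statistics for colony-formation assays; fold-change, PCA and
    rank-based group testing for flow-cytometry subset-count tables; and a
    single-cell RNA-seq toolkit (QC and CP10K normalization, kNN label
    transfer, neighborhood density enrichment, replicate-combined differential
    expression with Fisher's method, per-gene gaussian GLM likelihood-ratio
    tests, expression-matched gene-set scoring, and cell-cycle phase
    assignment). A seeded synthetic-data generator emulates all input data
    structures so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
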