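Package: gpsig
Title: Genetic-Programming Prognostic Gene Signatures from qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and external validation of small dichotomous gene
    signatures for 36-month cancer recurrence from qPCR (TaqMan) panels.
    Implements Ct quality screening and housekeeping-gene delta-Ct
    normalization, genetic-programming induction of algebraic classifier
    rules under a constrained grammar (bounded gene count and depth,
    protected arithmetic), cross-validated AUC fitness, gene-use frequency
    analysis, best-rule selection on a reserved test set, slice-point
    refinement by the Youden index, and a validation statistics battery:
    exact binomial (Clopper-Pearson) confidence intervals, exact McNemar
    comparisons, Kaplan-Meier / log-rank / Cox proportional-hazards
    analyses with backward elimination and a forced covariate, and a
    clinicopathologic guideline baseline classifier. A synthetic-cohort
    generator with planted rules and hazard ratios makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
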