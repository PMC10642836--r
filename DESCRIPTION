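Package: rbdge
Title: Digital Gene Expression Analysis of Retinoblastoma Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for NanoString nCounter digital
    gene expression profiling of undifferentiated versus differentiated
    retinoblastoma. Implements RCC lane-file input, positive-control technical
    normalization with negative-control background subtraction, reference-gene
    biological normalization, a one-sided t-test noise filter, two-group
    differential expression with Shapiro-Wilk test branching and false
    discovery rate control, clinical contingency-table statistics, ROC-based
    composite biomarker scoring with bootstrap validation and a nonlinear
    least-squares probability model, conditional inference trees with
    leave-one-out cross-validation, and ternary pathway-state overlays. A
    negative-binomial cohort simulator with known ground truth makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
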