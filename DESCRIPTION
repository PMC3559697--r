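Package: exomiR
Title: Permutation Statistics and Classification for Exosomal miRNA
    Profiling in Small Psychiatric Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for multiplexed bead-array miRNA
    expression profiles from small clinical cohorts (controls, bipolar
    disorder, schizophrenia). Implements moderated multiclass z-scores
    with an exchangeability constant, permutation q-values and windowed
    local false discovery rates, Holm step-down correction, exact
    Wilcoxon rank-sum verification, centroid-correlation hierarchical
    clustering on cube-root transformed profiles, nearest shrunken
    centroid classification with cross-validated misclassification
    curves, medication drug-class covariate adjustment by z-score
    subtraction, and qPCR delta-Ct relative quantification against a
    reference miRNA. Includes a seeded synthetic-data generator with a
    machine-readable truth table so the whole pipeline is testable
    without access to the original instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, DifferentialExpression,
    Classification, Clustering, qPCR
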