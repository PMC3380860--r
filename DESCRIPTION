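Package: specifex
Title: Disease-Specific Transcriptomic Deregulation Analysis for
    eIF2B-Related Leukodystrophy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying disease-specific transcriptomic
    deregulation in eIF2B-related leukodystrophy from matched
    patient/control fibroblast couples. Implements reference-channel
    correction of two-channel microarray intensities, gene-wise
    multi-factor ANOVA with Benjamini-Hochberg false discovery rate
    control, dual-cohort specificity selection with expression-rate
    thresholds, hypergeometric z-score process enrichment against GMT
    gene sets, delta-delta-Ct qPCR quantification with Mann-Whitney
    group tests, cross-platform concordance testing via the Fisher Z
    transform, and developmental splice-isoform ratio analysis
    (PLP/DM20, GFAP alpha/delta). A synthetic-data generator emulating
    the matched-couple dual-cohort study design makes the full pipeline
    testable end to end without access to primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
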