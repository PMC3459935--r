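Package: dietexpr
Title: Adipose Tissue Gene Expression Analysis for Dietary Intervention Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for adipose-tissue gene-expression studies of
    multi-centre dietary weight-loss interventions. Covers RT-qPCR plate
    quality control and normalization (delta-Ct against a reference gene,
    quantile, rank-invariant, geNorm reference-gene ranking, calibrator-based
    method comparison, k-nearest-neighbour imputation), derivation of clinical
    phenotypes (BMI, HOMA-IR, metabolic syndrome, weight-change groups),
    gene-by-gene linear mixed-model screening with Tukey visit contrasts and
    Benjamini-Hochberg FDR control, joint two-group sparse Gaussian graphical
    model inference with intertwined covariances and partial-correlation edges,
    and cis-eQTL allele-dose association with Hardy-Weinberg and call-rate
    filters. A synthetic cohort generator reproduces the statistical structure
    of a three-visit weight-loss trial and provides ground truth for recovery
    and false-discovery-rate testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    limma,
    igraph,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
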