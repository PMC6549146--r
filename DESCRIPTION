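Package: methylCKD
Title: Kidney Cytosine Methylation Analysis and CKD Progression Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for epigenome-wide association analysis of Illumina
    450k-style kidney methylation data and for modelling chronic kidney
    disease progression. Covers array quality control (detection-p and
    annotation filters, gap-signal probe detection, bisulfite-conversion
    scoring, beta-mixture quantile normalization, M-value transform, PCA
    outlier flagging), covariate-adjusted probe-wise association with
    interstitial fibrosis or eGFR with Benjamini-Hochberg correction and
    directional two-cohort replication, BLUP-adjusted longitudinal eGFR
    slopes, an inverse-variance-weighted progression model with LASSO
    variable selection and per-probe AIC augmentation, chromatin-state
    enrichment by Fisher test and probe resampling, and cis
    methylation-expression (eQTM) mapping with a permutation null. A seeded
    synthetic-cohort generator provides ground-truth fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
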