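Package: ColoType
Title: Consensus Molecular Subtyping of Colorectal Tumors by Multigene
    Risk Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous and discrete consensus molecular subtype (CMS)
    classification of colorectal cancer tumors from whole-genome or
    targeted RNA-seq gene expression. Implements pseudo-reference
    size-factor normalization for count matrices, per-gene risk scores
    built by bootstrapped Gaussian mixture modeling, multigene risk
    score (MRS) subtype scores calibrated as monotone positive
    predictive value curves, multi-cohort consensus panel selection,
    Youden-index classification thresholds with mixed-type reporting,
    derived CRCassigner-style scores, single-sample prediction against
    a serialized reference set, and a seeded multi-cohort synthetic
    data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    caret,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
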