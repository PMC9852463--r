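Package: skillseq
Title: Automated Surgical Skill Assessment from Bimanual Tool-Motion Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summative and formative assessment of laparoscopic surgical skill
    from per-frame tool-motion traces (instrument centroids extracted from
    task video). Provides preprocessing of variable-length bimanual
    coordinate sequences (gap interpolation, downsampling, normalization), a
    denoising-autoencoder embedding, an attention-infused residual 1D
    convolutional network with global average pooling for pass/fail
    classification and continuous score regression, cross-validation schemes
    used in surgical data science (stratified k-fold, leave-one-supertrial-out,
    leave-one-user-out), trustworthiness quantification (question-answer
    trust, trust densities, trust spectrum, NetTrustScore), class-activation-map
    saliency for formative feedback, and a statistical validation of saliency
    by CAM-masked retraining. Includes a seeded generator of synthetic
    pattern-cutting-style trials with ground-truth struggle windows so the
    whole pipeline is testable without access to proprietary datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    pROC,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
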