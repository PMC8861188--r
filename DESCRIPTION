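Package: voicefev
Title: Predicting Lung Function from Voice Recordings via Breath and Speech Acoustics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline that predicts forced expiratory volume
    (FEV1 percent predicted) and its categorical severity from recorded voice.
    Recordings are separated into breath and speech segments by a calibrated
    threshold vote over five discriminative frame-level acoustic features;
    per-segment-kind feature means are aggregated into a 23-feature recording
    vector, optionally extended with biological covariates, and fed to random
    forest, radial-kernel support vector machine and linear models for three
    tasks: FEV1 percent regression, severity grading, and normal/abnormal
    classification. Train/test partitions can be balanced over 5-point FEV1
    percent bins so both splits share the target distribution. Because the
    underlying clinical audio is not publicly deposited, the package includes
    a seeded synthetic-cohort generator with a documented FEV1-to-acoustics
    link and ground-truth segment labels, so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    withr,
    randomForest,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
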