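Package: spindetect
Title: Detection of Trained Spin-Alert Behaviour from Collar-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for recognising a trained canine alert
    behaviour (two consecutive clockwise 360-degree body rotations) in
    six-channel collar IMU recordings sampled at 50 Hz. Provides a
    statistical simulator of multi-subject labelled recordings, readers and
    writers for the Consensys-style CSV export, sliding-window segmentation
    with a majority labelling rule, temporal and spectral feature
    engineering with a three-stage selection pipeline (variance filter,
    collinearity filter, ANOVA F-test), a tuned gyroscope-magnitude
    heuristic baseline plus four supervised classifier families, and dual
    segment-level and event-level evaluation under within-subject and
    leave-one-dog-out protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
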