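Package: kinegram
Title: Activity Recognition from Wearable Inertial Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for recognizing short athletic movements
    (jogs, sprints, passes, shots, jumps) in multi-location inertial
    measurement unit recordings. Provides a synthetic corpus generator for
    scripted activity sessions, threshold-based activity isolation with an
    interquartile-range periodic/explosive discriminator, windowed dataset
    construction with max-abs scaling and undersampling balance, a family of
    convolutional network variants with signal-, sensor- and array-level
    weight sharing combined with (bi)directional LSTM heads trained by ADAM
    with staged learning-rate schedules, and a gated sliding-window evaluator
    with best-score postprocessing and duration-based outlier removal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
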