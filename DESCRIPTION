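Package: kneehar
Title: Hierarchical Activity and Gait-Phase Recognition from Wearable IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A hierarchical human-activity-recognition (HAR) pipeline for
    lower-limb inertial measurement unit (IMU) recordings, aimed at people
    with knee osteoarthritis. Provides a synthetic-cohort simulator for
    labeled four-sensor (bilateral thigh/shank) 100 Hz recordings of chair
    transitions, stair negotiation and walking; time synchronization by
    normalized cross-correlation; sliding-window segmentation with 0-255
    image encoding of the 24 accelerometer/gyroscope channels; six small
    convolutional neural network classifiers arranged in a three-level
    decision tree (activity, direction, stance/swing phase); and
    participant-wise leave-one-out cross-validation with per-node confusion
    matrices, accuracy, precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
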