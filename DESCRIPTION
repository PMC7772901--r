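Package: wearnet
Title: Deep Neural Networks for Stress and Affect Detection from Wearable
    Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stress detection and 3-class affect classification from raw
    multimodal wearable sensor streams. Implements a multi-branch deep 1D
    convolutional network for chest-worn sensors (ECG, EDA, EMG, respiration,
    skin temperature, 3-axis accelerometer, all 700 Hz) and a multilayer
    perceptron for wrist-worn sensors (BVP 64 Hz, 3-axis accelerometer 32 Hz,
    EDA 4 Hz, skin temperature 4 Hz), together with the full pipeline: record
    reading and validation, fixed-duration windowing of multi-rate signals,
    window-label assignment, scrambled hold-out splits and k-fold
    cross-validation, seeded training with Adam and cross-entropy losses, and
    confusion-matrix metrics (accuracy, precision, recall, F1). A synthetic
    multimodal-signal generator with condition-dependent statistics makes
    every stage runnable and testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
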