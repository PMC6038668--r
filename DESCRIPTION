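Package: gaitnarx
Title: Abnormal Gait Detection from Accelerometer Data via NARX Walking Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for real-time abnormal-gait detection from tri-axial
    accelerometer recordings. A subject's normal walk is modelled with an
    output-only nonlinear autoregressive (NARX) model built from a sigmoid
    basis-function expansion (a linear ARX variant is included); sliding
    windows of new walking data are then classified as normal or abnormal by
    thresholding the FIT statistic of one-step-ahead predictions. Also
    provides classical comparator features for accelerometer gait analysis
    (Hjorth parameters, signal energy, signal magnitude area and vector, peak
    statistics, co-occurrence matrix features), a seeded synthetic gait
    simulator for normal and obstacle-perturbed walks, and an evaluation
    harness with cross-validation and detection-latency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
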