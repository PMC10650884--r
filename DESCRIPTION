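Package: bradynet
Title: Masked Pre-Training and Transfer Learning for Wearable-Sensor
    Motor-Impairment Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for grading motor impairment severity
    from two-sensor limb accelerometer recordings of repetitive
    MDS-UPDRS-style movement tasks. Raw tri-axial recordings are reduced to
    resultant acceleration, jerk and windowed root-mean-square channels,
    segmented into standardized five-second windows, and classified as low
    versus high impairment by an XceptionTime-style one-dimensional
    convolutional network. The network can be pre-trained without labels by
    reconstructing geometrically masked spans of the input, and the learned
    backbone weights transferred into supervised classifiers under
    fine-tune-last-then-all or fine-tune-all schemes. Grouped stratified
    K-fold splitting prevents segment-level leakage, max-vote inference
    aggregates window predictions per recording, Gaussian-noise probing
    measures robustness, and linear centered kernel alignment (CKA)
    compares learned representations across training-set and
    initialization choices. A synthetic-cohort generator with
    severity-dependent movement phenomenology (amplitude decrement, 4-6 Hz
    tremor, hesitations) makes the whole pipeline testable without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
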