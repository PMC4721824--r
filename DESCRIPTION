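Package: softgait
Title: Soft Biometrics from Wearable Inertial Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-step gait analysis pipeline for 6-channel inertial
    measurement unit (IMU) recordings: moving-average smoothing, step
    decomposition by peak/valley detection on the cranio-caudal acceleration
    axis, extraction of a 50-dimensional per-step feature vector (time- and
    frequency-domain statistics per channel), and random-forest classification
    of soft-biometric attributes (gender, age group, height group) under
    stratified k-fold and subject-wise (leave-one-subject-out)
    cross-validation, with permutation feature importance, random-forest
    regression of age and height, and within-sequence step-consistency
    statistics. Includes a demographically conditioned synthetic walking-IMU
    generator with ground-truth step boundaries for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
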