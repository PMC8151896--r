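Package: mocapselect
Title: Training-Data and Sensor-Placement Selection for Sparse Inertial
    Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building sparse inertial (IMU) motion-capture
    pipelines: skeleton kinematics (sensor-to-bone calibration, root-bone
    normalization, rotation conversions, angular error), a synthetic
    multi-activity motion generator with controllable inter-bone coupling,
    KL-divergence-based selection of independent-and-identically-distributed
    training segments from a large motion corpus to match a small reference
    sample, maximal-information-coefficient (MIC) based
    max-relevance/min-redundancy greedy placement of sparse sensors on a
    21-bone body, and a compact bidirectional LSTM posture reconstructor
    that maps selected-bone measurements to unselected-bone posture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
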