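Package: gaitesn
Title: Ground Reaction Force and Gait Event Prediction from Single-IMU
    Acceleration with Echo State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts multidimensional ground reaction force (GRF) and five
    stance-phase gait events (heel strike, heel push, foot flat, toe push,
    toe off) from tri-axial accelerations of a single inertial measurement
    unit, using a leaky-integrator echo state network with a ridge-regression
    readout.  Includes a seeded synthetic gait-data generator (healthy and
    medial knee osteoarthritis profiles), vertical-GRF event labelling,
    standard and Gaussian-kernel (temporal-parameter weighted) readout
    training, record-weighted mean-absolute-error scoring over gait-cycle
    zones, and a sweep over sensor locations and acceleration-axis
    combinations to rank sensor placements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
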