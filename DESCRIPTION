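Package: sprintldm
Title: Sprint Kinematics from Laser Distance-Measurement Traces
Version: 0.1.0
Authors@R:
    person("Sprint", "Biomechanics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns raw 100 Hz laser distance-measurement (LDM) traces of a
    linear sprint into calibrated displacement, running speed, acceleration,
    speed zones, 10 m section splits, per-step phase timings (support, flight,
    step), step length and frequency, and left-right gait symmetry.  Includes
    artifact detection and repair for beam dropouts and spikes, rule-based
    start- and end-point detection, descriptive statistics, machine-readable
    report export, and a synthetic-trace simulator with per-step ground truth
    so that every processing stage can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
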