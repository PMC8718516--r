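Package: otassess
Title: Multisensor Upper-Limb Assessment for Occupational Therapy
Version: 0.1.0
Authors@R:
    person("OT", "Assess Developers", email = "otassess@example.org",
           role = c("aut", "cre"))
Description: Tools for instrumented assessment of upper-limb function during
    occupational-therapy (OT) exercises. Fuses depth-camera and wearable-IMU
    joint trajectories with a scalar Kalman filter, scores movement completion
    against healthy reference motion using Pearson correlation with dynamic
    time warping, automatically segments surface-EMG recordings into movement
    bursts via an integrated-EMG interval-scoring recursion, and classifies
    the OT action type with a four-branch one-dimensional convolutional
    network. Includes a synthetic-data generator emulating the acquisition
    protocol (two kinematic sensors, three sEMG channels, four standardized
    actions, graded impairment severity) so that the full pipeline is testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
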