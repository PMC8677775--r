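Package: errpirl
Title: Closed-Loop Personalization of Robot Obstacle Avoidance from
    EEG Error-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a shared-control
    brain-computer interface in which a robot arm's obstacle-avoidance
    behavior is adapted to a user's preference. A linear dynamical
    system generates planar reaching trajectories that are locally
    modulated around a spherical obstacle by two parameters, a safety
    factor and a reactivity. A single-trial EEG decoder detects
    error-related potentials (ErrPs) elicited when a trajectory
    violates the user's preferred clearance, using a canonical
    correlation spatial filter, temporal, spectral and Riemannian
    tangent-space covariance features, and diagonal linear discriminant
    analysis with continuous sliding-window decoding. Decoder
    posteriors weight demonstrated trajectories in a Gaussian-process
    inverse reinforcement learning scheme that infers a reward field
    over the workspace and maps it back to modulation parameters.
    Includes a Stockwell-transform time-frequency module, a synthetic
    EEG and simulated-user generator, evaluation metrics, and the full
    calibration-adaptation closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
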