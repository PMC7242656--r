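Package: reachopt
Title: Muscle-Driven Arm Reaching Under Optimality Principles via Bayesian Optimization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-dynamics simulation of a planar two-joint, six-muscle human
    arm with Hill-type muscle-tendon units (contractile, parallel-elastic,
    serial-elastic and serial-damping elements) and Hatze-style activation
    dynamics. Nine candidate optimality principles (angle acceleration, hand and
    angle jerk, torque, torque change, absolute mechanical work, stimulation
    effort, and jerk/energy/effort hybrids) are evaluated on simulated
    point-to-manifold reaching movements toward a vertical bar. Open-loop muscle
    stimulations are searched with a from-scratch Gaussian-process Bayesian
    optimizer using an upper-confidence-bound acquisition, with a random-search
    baseline. Includes trajectory post-processing (zero-phase Butterworth
    filtering, movement windowing, signed curvature, velocity-profile skewness),
    comparison metrics against reference kinematics, a synthetic reference-data
    generator, and experiment drivers with a thin command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
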