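Package: kinecode
Title: Single-Trial Kinematic Coding Analysis for Occluded Action Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates temporally occluded reach-to-grasp two-alternative
    forced-choice experiments and analyses them with a single-trial kinematic
    coding framework: empirical and piecewise change-point psychometric models
    (logistic mixed effects), confidence-accuracy calibration ratios, L2
    regularized logistic encoding models of object-size information in movement
    kinematics, per-observer readout models with cross-validated accuracy and
    permutation chance levels, evidence-independent bias decomposition, and
    alignment of readout weights against encoding weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
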