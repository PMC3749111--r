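Package: ecogtraj
Title: Decoding Three-Dimensional Arm Trajectories from ECoG Band-Power Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous decoding of three-dimensional arm
    kinematics (shoulder/elbow joint angles and joint coordinates) from
    multichannel electrocorticographic (ECoG) recordings. Raw signals are
    common-average referenced, split into seven sensorimotor-rhythm bands with
    Butterworth filters, rectified, low-pass smoothed into amplitude
    envelopes, downsampled and z-scored; a lagged linear decoder over the past
    second of envelopes is fit per kinematic variable by sparse Bayesian linear
    regression (automatic relevance determination) with early stopping.
    Includes velocity-threshold trial segmentation, leave-one-out
    cross-validated evaluation (Pearson correlation and normalized RMSE),
    per-band contribution analysis, a four-degree-of-freedom shoulder-elbow
    kinematic model for reconstructing 3D trajectories from decoded joint
    angles, and a fully deterministic synthetic-session generator for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
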