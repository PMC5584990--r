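Package: magtrack
Title: Magnet-Based Eye Tracking: Simulation, Calibration and Oculomotor Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for magnet-based eye tracking in head-fixed and freely
    moving mice. Provides a forward model of a two-channel anisotropic
    magnetoresistive (AMR) angle sensor responding to an implanted magnet,
    dual-angle video-oculography geometry that converts pupil/corneal-reflection
    landmarks into angular eye position without knowledge of the pupil-to-corneal
    curvature distance, pupil and corneal-reflection detection from eye-camera
    frames (circular Hough localization, reflection masking, Starburst ray
    casting with consensus ellipse fitting), signal conditioning (zero-phase
    low-pass filtering, sliding-window differentiation, velocity-threshold
    desaccading, LED-flash stream alignment), position- and velocity-based
    calibration of sensor voltages into eye angle (ordinary and ridge regression
    with blocked cross-validation, sine-amplitude ratios), and oculomotor
    metrics (VOR/OKR gain and phase, spatial resolution, overhead-video motion
    indexing, binocular divergence, eye-head velocity relation). A synthetic
    session generator produces every observable stream with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
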