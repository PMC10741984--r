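Package: cfmest
Title: Sensor-Free Estimation of Ground Contact Forces and Moments from Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the ground contact forces and moments (CFMs) under each
    foot of an articulated human (or human-exoskeleton) model from joint
    kinematics alone, without force plates or instrumented insoles. The
    double-support contact wrench, statically indeterminate in a fixed frame,
    is decomposed in a dynamic decoupled coordinate system (DDCS) whose X axis
    joins the two feet's centres of pressure; this reduces the twelve unknown
    contact components to two scalar parameters, which are then resolved by
    minimising a stiffness-weighted sum of squared joint moments over a grid
    traversal with a closed-form inner minimiser. Includes rank-analysis
    utilities for the underlying force-balance system, a recursive
    Newton-Euler inverse-dynamics engine, a synthetic-gait generator with
    ground-truth contact wrenches for validation, and calibration of the
    joint weight factors against reference contact forces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
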