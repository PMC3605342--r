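Package: ankleqs
Title: Ankle Quasi-Stiffness and Propulsive Work During Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and statistical modelling of the quasi-stiffness and
    propulsive mechanical work of the human ankle during the stance phase of
    level-ground walking. Provides a synthetic stance-phase gait generator
    with known ground truth, moment-angle loop segmentation into dorsi-,
    dual- and plantar-flexion phases, least-squares quasi-stiffness and
    loop-work extraction, foot-segment inverse-dynamics auditing, partial
    least squares leave-one-subject-out cross-validation, backward stepwise
    regression model selection, and stature-based model reduction via the
    Froude-number preferred walking speed, for sizing compliant ankle
    prostheses, orthoses and exoskeletons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
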