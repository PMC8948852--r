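Package: kinarom
Title: Skeleton-Based Upper-Limb Active Range of Motion and Fugl-Meyer Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated assessment of upper-limb motor performance in
    children from markerless 25-joint skeleton streams (Kinect-v2 layout).
    Computes shoulder and elbow joint angles with the two-vector included-angle
    formula, reduces measurement sessions to active range of motion (AROM)
    summaries, scores the automated flexor-synergy items of the Fugl-Meyer
    upper-extremity assessment, classifies motor capacity, and compares groups
    with a Wilcoxon rank-sum test (exact enumeration with mid-ranks or
    tie-corrected normal approximation). A forward-kinematics motion simulator
    generates noisy seated shoulder-abduction and elbow-flexion skeleton
    streams under calibrated distance/illumination noise presets, so the whole
    measurement chain is testable without a physical depth sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
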