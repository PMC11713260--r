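Package: doseAccum
Title: Deformable CT-to-CBCT Registration and Dose Accumulation for
    Fractionated Pelvic Radiotherapy
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate cumulative dose in fractionated pelvic
    radiotherapy from weekly cone-beam CT (CBCT). Provides synthetic
    deformable pelvis phantoms with analytic ground-truth displacement
    fields, rigid and multi-resolution demons-style deformable image
    registration, extended field-of-view merged-CBCT construction via a
    limiting contour, contour propagation with Dice and target
    registration error scoring, a simplified anatomy-responsive
    four-field dose engine, displacement-field-based dose deformation
    and spatial accumulation, and a dosimetric evaluation layer
    (dose-volume-histogram metrics, percent-difference banding, exact
    Wilcoxon signed-rank testing, and 3D gamma analysis). Ships the
    per-patient summary tables of a published 20-patient cervical-cancer
    CBCT dose-accumulation study as plain-text fixtures so its reported
    summary statistics can be recomputed exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
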