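Package: radtilt
Title: Automatic Volar Tilt and Radial Inclination from 3D Radius Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic, knowledge-based measurement of volar tilt and
    radial inclination on 3D surface models (STL) of the whole radius. The
    pipeline estimates a canonical pose from inertia axes and cross-section
    circularity, detects the clinical landmarks of the distal radius (radial
    styloid, ulnar volar and dorsal corners, central reference point, dorsal
    and volar cortical-margin reference points), constructs a 2D-equivalent
    anatomical coordinate system with the longitudinal axis taken from the
    28.8-53.3 mm mid-shaft segment proximal to the central reference point,
    and computes the two angles with conventional radiographic sign
    conventions. Also included: Bland-Altman agreement statistics with
    limits-of-agreement uncertainty, landmark-discrepancy metrics, and a
    parametric generator of radius-like meshes with annotated ground truth
    for validation, including simulated dorsally or volarly angulated
    metaphyseal malunions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
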