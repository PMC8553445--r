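Package: mlcoffset
Title: Leaf-End Offset Corrections for Carbon-Ion Multileaf Collimators
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the on-axis 50%-dose position of a rectangular
    multileaf-collimator (MLC) leaf end in a diverging carbon-ion beam and
    the resulting treatment-planning offset (X50 - Xmlc) and
    light-radiation agreement (Xtang - X50). The leaf edge is modelled by
    single-exponential survival of beam nuclei along the slant chord
    through the leaf material; the 50% ray is found by a fixed-point
    chord solve. Includes a material database for nine candidate leaf
    alloys, a virtual-source estimator from field-size magnification at
    displaced planes, ray-traced transmission profiles with edge-metric
    extraction, a monotone film-calibration (H-D curve) fit, and
    regeneration of the per-field offset tables, with an optional
    forensic mode emulating 4-decimal radian quantization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
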