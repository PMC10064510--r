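Package: stomapipe
Title: Calibrated Stomatal Phenotyping from Handheld-Microscope Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for rapid stomatal phenotyping from brightfield
    leaf-surface micrographs taken with a handheld microscope. Converts
    pixel measurements to physical units through per-lens optical
    calibration profiles, detects stomata with a classical template
    matcher or by reading externally produced detections, delineates
    stomatal complexes and apertures and derives per-stoma traits
    (area, length, width, aperture, openness) and per-image summaries
    (count, density), evaluates detections against ground truth with
    IoU-matched precision, recall and F1, compares automated against
    manual measurements by linear regression, and screens image cohorts
    for contrasting density/size phenotypes. A deterministic synthetic
    leaf-epidermis generator with exact per-stoma ground truth lets the
    whole chain run and be tested without real images or trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    polyclip,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
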