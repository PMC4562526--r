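Package: airwaymorph
Title: Airway Wall Morphometry from Endobronchial Ultrasound and Histology
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometric morphometry of layered airway cross-sections as imaged
    by radial endobronchial ultrasound (EBUS) or measured on histological
    sections. Provides synthetic airway phantoms with known ground truth,
    contour-based measurement of internal perimeter, diameter, lumen area and
    layer thicknesses with quality-control and partial-scan completion rules,
    the concentric-annulus model converting wall-layer areas into equivalent
    distended-airway thicknesses and submucosal composition, Bland-Altman and
    intraclass-correlation agreement statistics for paired modalities, nested
    variance-component estimation, image-replicate optimization and
    simulation-based power analysis for hierarchical (group/subject/airway/
    image) study designs, plus file formats and a pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
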