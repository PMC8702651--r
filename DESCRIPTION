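Package: mrvs
Title: Multi-Branch Retinal Vessel Segmentation and Quantification for
    OCTA En-Face Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments retinal vessels on en-face optical coherence
    tomography angiography (OCTA) images with a two-branch oriented
    line-detector pipeline (a large-vessel branch and a capillary branch
    fused by union), detects the foveal avascular zone (FAZ) and
    non-perfusion regions, and quantifies 24 standard vascular and FAZ
    metrics including skeleton density, vessel diameter/complexity/
    perimeter indices and box-counting fractal dimension. Includes a
    synthetic angiogram phantom generator with pixel-exact ground truth,
    segmentation-evaluation metrics (sensitivity, specificity, accuracy,
    Dice, Matthews correlation, vessel volume difference) and test-retest
    repeatability statistics (within-subject SD, coefficient of
    variation, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
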