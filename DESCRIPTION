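Package: octaquant
Title: Quantification of En-Face OCT Angiography Images with Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies en-face optical coherence tomography angiography
    (OCTA) scans of the macula: Gabor- and Hessian-based large-vessel
    enhancement and segmentation of the superficial capillary plexus,
    mean-intensity binarization of the capillary plexuses with foveal
    avascular zone (FAZ) masking, choriocapillaris flow-void thresholding
    at one standard deviation below the mean, Bennett axial-length
    magnification correction of a fovea-centered annulus (inner diameter
    1.0 mm, outer diameter 2.5 mm), and the derived per-eye outcomes
    (perfusion densities with and without large vessels, FAZ area and
    circularity, choriocapillaris flow deficit). Includes a synthetic-eye
    and synthetic-cohort generator with controllable ground truth for
    validation, and cohort statistics with normality-gated univariate
    tests and linear generalized estimating equations that account for
    inter-eye correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
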