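Package: fstloc
Title: Simulation-Based Functional Localization of Putative Human Area FST
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-data pipeline for functionally localizing the putative
    human homolog of macaque area FST (pFST) and distinguishing it from the
    neighboring hMT/MST motion complex. Constructs block-design 2D-motion,
    changing-disparity stereomotion and opponent-motion localizer stimuli and
    population receptive field (pRF) mapping apertures; simulates vertex-wise
    BOLD time series on a synthetic cortical sheet with ground-truth regions;
    estimates responses with a boxcar-times-hRF general linear model and forms
    localizer contrasts; fits a 2D circular-Gaussian pRF model and a
    stimulus-contrast null model by coarse-to-fine optimization; automates
    percentile-threshold ROI delineation with overlap metrics (DICE, centroid
    distance, surface area); and reproduces the pRF size/eccentricity
    estimation-bias simulation together with the group-level validation
    statistics (motion opponency, R1 myelin proxy).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
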