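Package: octasym
Title: Intereye Asymmetry Analysis of OCTA En-Face Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies retinal microvasculature on en-face optical
    coherence tomography angiography (OCTA) images and compares fellow
    eyes across diabetic retinopathy stages. Implements global
    mean-plus-coefficient-times-SD intensity thresholding with big-vessel
    exclusion, ETDRS-grid sector vessel density, box-counting fractal
    dimension, foveal avascular zone area, perimeter and circularity from
    a traced boundary, per-patient absolute intereye differences and
    asymmetry indices, and the cohort-level statistical analysis
    (Kruskal-Wallis, Wilcoxon signed-rank, linear mixed models with a
    patient random intercept and a stage-by-side interaction). Includes a
    synthetic angiogram and cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
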