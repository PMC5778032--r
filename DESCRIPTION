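Package: vifc
Title: Vertex-Wise Index of Functional Criticality for Surface fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Surface-based detection of imminent critical transitions in
    resting-state fMRI. Computes the vertex-wise Index of Functional
    Criticality (vIFC), a dynamical-network-biomarker statistic defined as the
    BOLD standard deviation times the mean Pearson correlation within a
    vertex's second-order mesh neighborhood divided by the mean correlation
    with vertices outside it. Includes triangulated cortical surface I/O
    (FreeSurfer binary, GIFTI, plain text), FWHM-calibrated surface smoothing,
    a vertex-wise group GLM with per-group offsets and slopes,
    Benjamini-Hochberg FDR control, suprathreshold cluster extraction,
    behavioral partial correlations, summary-statistic ANOVA and chi-square
    tests, and a synthetic icosphere plus AR(1) latent-factor simulator for
    offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
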