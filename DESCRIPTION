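Package: rpcavg
Title: Quantifying Radial Peripapillary Capillary Visualization Under
    OCTA Frame Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an en-face optical coherence tomography
    angiography (OCTA) frame registration and averaging pipeline for the
    radial peripapillary capillary (RPC) network: synthetic capillary
    scene simulation, rigid stack registration, peripapillary region of
    interest placement around a fitted optic disc ellipse, vessel
    quantification (mask-based signal-to-noise ratio, skeleton endpoints,
    mean segment length, capillary length density, intercapillary
    distance), and the repeated-measures statistics (Greenhouse-Geisser
    corrected RM-ANOVA with sequential Bonferroni post hoc tests) used to
    determine the optimal number of averaged frames per metric.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    Matrix,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
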