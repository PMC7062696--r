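Package: radiocell
Title: Single-Cell Multimodal Radiography: Dry Mass, Cell Cycle and Radiotracer Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell multimodal radiography of radiolabelled cells
    grown on a scintillator: quantitative phase microscopy (off-axis interferogram
    demodulation, two-dimensional phase unwrapping and dry-mass computation),
    FUCCI two-channel fluorescence normalisation and cell-cycle classification,
    radioluminescence microscopy event detection with morphological track
    filtering and radioactive-decay correction, phase-based cell segmentation
    with point-spread-function dilation, and the accompanying statistics
    (median/IQR summaries, exact and approximate Mann-Whitney tests, one-way
    ANOVA, and Huber-weighted iteratively reweighted least-squares regression).
    A seeded synthetic-data generator emulates the full acquisition so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
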