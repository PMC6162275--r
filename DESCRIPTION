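Package: hsafm
Title: Simulation and Analysis of High-Speed AFM Topograph Movies of Channel 2D-Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for high-speed atomic force microscopy (HS-AFM)
    topography of membrane-protein 2D-crystals, built around a synthetic
    topograph-movie generator with known ground truth. Renders tetragonal
    crystals of tetrameric channel footprints (two packing polymorphs),
    applies spherical-tip dilation, scan noise and drift; provides first-order
    plane flattening, subpixel cross-correlation drift registration, lattice
    detection by autocorrelation peak picking, correlation averaging with C4
    symmetrization, height-class and radial-distance morphometry, a
    border-nucleated domino model of conformational-state kinetics on the
    lattice, rigid-footprint rotation fitting, an iris-diaphragm lever
    calculator, and a two-state single-channel current simulator with
    half-amplitude idealization and open-probability estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    tiff,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
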