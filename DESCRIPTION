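Package: beadscreen
Title: Simulated Dual-Function Liquid Handling and In-Situ Hydrogel Bead Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully software-simulated model of a pipetting robot that doubles
    as an in-situ imaging platform for ionically crosslinked hydrogel beads.
    Provides a virtual 11-slot deck with Opentrons-style labware definitions,
    a protocol planner and state-machine simulator for two-pipette hydrogel
    screens with friction-fit camera tool changes, a capture-on-message camera
    service, a synthetic well-image generator with gelation and disintegration
    ground truth, and the inverse analysis pipeline: bead isolation by
    enhancement plus thresholding, 8-bit pixel-intensity quantification,
    concentration-screen summaries, and disintegration kinetics fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
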