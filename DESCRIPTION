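Package: pfoce
Title: Light-Sheet Photonic-Force Optical Coherence Elastography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse reconstruction for light-sheet
    photonic-force optical coherence elastography (LS-pfOCE). Models the
    radiation-pressure force of an astigmatic Gaussian light sheet on
    Mie-regime probe beads via generalized Lorenz-Mie theory, reconstructs
    the local complex shear modulus G* = G' + iG'' around each bead from
    phase-sensitive OCT data using Oestreicher's oscillating-sphere model,
    measures 2D force profiles from bead trajectories in viscous fluid with
    a Radon-transform velocimeter, and provides downstream analyses of
    pericellular stiffness gradients, collagen shell metrics, and
    bead-displacement statistics. Includes synthetic-data generators that
    emulate oscillating-bead phase signatures, speckle, photothermal phase
    modulation, and shot-noise-limited phase noise, so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    signal,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
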