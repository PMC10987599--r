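Package: sweptsheet
Title: Dual-Foci Axially Swept Light-Sheet Microscopy Simulation and Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and acquisition-planning toolkit for axially
    swept light-sheet microscopy (ASLM) with a dual-foci rolling-shutter mode.
    Models Gaussian light-sheet beams, multi-immersion magnification scaling
    and the system point spread function; generates rolling-shutter row
    schedules, sawtooth focus-actuator waveforms and focus trajectories for
    single-focus and dual-foci operation; renders camera frames and stacks
    from synthetic phantoms under a Poisson/Gaussian sCMOS noise model; plans
    tile grids with acquisition-time and data-size budgets; classifies tile
    informativeness with an intensity-difference rule and a small
    convolutional network trained in base R; and quantifies resolution from
    bead stacks by Gaussian FWHM fitting with optional Richardson-Lucy
    deconvolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
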