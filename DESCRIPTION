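Package: bisectr
Title: Beam-Image-Shift Tomography Acquisition Geometry and Constrained
    Tomographic Reconstruction
Version: 0.1.0
Authors@R:
    person("bisectr", "developers", email = "bisectr@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for multi-target cryo-electron tomography
    acquisition and processing. Implements grouped dose-symmetric tilt-scheme
    generation and validation, rotation geometry about the tilt axis with
    per-target eucentric-height fitting, iterative two-level tracking on
    cosine-stretched images, a seeded closed-loop virtual-stage simulator,
    per-tilt astigmatic CTF estimation from tilt-corrected power spectra,
    and score-driven exposure-weighted Fourier reconstruction from particle
    projections extracted directly from tilt-series, with constrained
    rigid-body refinement and Fourier shell correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
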