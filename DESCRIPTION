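Package: pamdct
Title: One-Step Basis-Material Decomposition for Grating-Based Phase-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for grating-interferometer
    differential phase-contrast computed tomography. Implements the one-step
    PAMD-SART algorithm, which reconstructs two basis-material fraction maps
    directly from absorption and differential-phase sinograms by coupled
    view-wise SART updates with total-variation regularization, together with
    the two classical two-step baselines (projection-domain decomposition with
    integrated phase, and image-domain decomposition after filtered
    backprojection or regularized iterative reconstruction). A quantification
    layer converts decomposed maps to electron density, effective atomic
    number and virtual monochromatic attenuation images via a two-channel
    photoelectric/Klein-Nishina model, and includes a conditioning study
    comparing phase-absorption against dual-energy material decomposition.
    Synthetic head and four-rod phantoms with a bundled material table make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
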