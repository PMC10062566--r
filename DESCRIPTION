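Package: z2phase
Title: Phase-Encoded Diffusion MRI with Quadratic (Z2) Gradient Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and analytic toolkit for diffusion MRI in which
    diffusion is encoded in the signal phase by a quadratic (Z2) gradient
    field rather than in the magnitude by a linear gradient. Provides
    closed-form net-phase models for anisotropic spin ensembles under Z2
    encoding, a seeded Monte Carlo spin-walk engine with per-step phase
    accumulation in free and cylinder-restricted geometries, a periodic
    fibre-phantom substrate generator with gamma-distributed radii, a
    Biot-Savart model of a modified Helmholtz gradient coil, and declarative
    experiment drivers with net-phase extraction, fractional-anisotropy
    recovery and baseline-corrected phase analysis of 1DFT line data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
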