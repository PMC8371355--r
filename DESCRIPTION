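Package: kgfr
Title: Creatinine Kinetics and the Kinetic Glomerular Filtration Rate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-compartment creatinine kinetics with a linearly changing
    volume of distribution. Provides the closed-form solution for serum
    creatinine over a clinical time interval, analytic sensitivities of the
    creatinine to the kinetic GFR and to the volume-change rate (including
    the removable-singularity limit branches), a seeded numerical sign scan
    verifying that the creatinine/GFR derivative is negative throughout the
    clinically valid parameter space, and inversion of the model to estimate
    the kinetic GFR from serial creatinine measurements. Includes a seedable
    synthetic-series generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
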