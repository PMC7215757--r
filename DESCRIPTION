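Package: releasemix
Title: First-Order Drug-Release Kinetics and Mixture Design for
    Microparticle Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the non-linear first-order model a*(1 - exp(-b*t)) to
    cumulative drug-release curves from polymeric microparticle
    formulations, predicts release from arbitrary blends of formulations
    by mass-weighted superposition, and inversely designs blend fractions
    that achieve a target release profile under a simplex constraint.
    Includes the supporting UV-vis quantification arithmetic
    (Beer-Lambert conversion, encapsulation efficiency,
    withdrawal-corrected cumulative release) and a synthetic-data
    generator with known ground truth so every pipeline stage is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
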