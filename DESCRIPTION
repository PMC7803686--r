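Package: sonodry
Title: Coupled Heat and Mass Transfer Modelling of Ultrasound-Assisted
    Hot-Air Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates convective hot-air drying of a shrinking spherical
    fruit (blackberry) with and without airborne or contact ultrasound
    assistance.  Solves the coupled one-dimensional spherical heat
    conduction and Fickian moisture diffusion equations by the method of
    lines, with a GAB sorption isotherm at the evaporating surface,
    temperature-dependent Arrhenius effective diffusivity, an empirical
    linear shrinkage law, and an acoustic heat flux in the surface energy
    balance.  Also provides the full parameter-estimation chain used to
    calibrate such models: GAB isotherm fitting, slope-method effective
    diffusivity, Arrhenius regression, lumped-capacitance heat transfer
    coefficient, Chilton-Colburn mass transfer coefficient, and
    calorimetric ultrasound power, together with seeded synthetic-data
    generators for every experimental input and arithmetic for
    cross-treatment comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
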