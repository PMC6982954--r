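Package: bmcal
Title: Bimaterial Microcantilever Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward thermal and deflection modelling of an optically heated
    bimaterial microcantilever used as a micro-calorimeter, and the inverse
    estimation of the heat capacity of a micro-scale sample (such as a single
    yeast cell) resting on the beam. Provides lumped-capacitance and
    one-dimensional distributed transient heat-transfer models, bimorph
    curvature mechanics, three-parameter exponential time-constant regression
    of tip-deflection traces, volume-weighted heat-capacity mixture inversion,
    a seeded synthetic trace generator with Gaussian noise, Monte Carlo
    parameter-recovery experiments, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
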