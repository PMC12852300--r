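Package: cellbp
Title: Basic-Pathways Kinetic Modeling of Compartmentalized Whole-Cell
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compartmentalized, element-balanced biochemical reaction
    networks with growth-dilution pseudo-reactions, assembles the
    volume-scaled stoichiometric matrix (S0 | -D), constructs a nonnegative
    null-space basis of Basic Pathways, solves for chemically feasible
    steady-state rate vectors from assigned independent rates,
    auto-generates and calibrates Michaelis-Menten, mass-action and
    transport rate laws, and integrates the regulated nonlinear ODE system
    under perturbations.  Ships a reduced iron-metabolism cell model and a
    seeded synthetic-network generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
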