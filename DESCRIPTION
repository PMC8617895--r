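Package: forcekin
Title: Force-Dependent Folding Kinetics from Single-Molecule Pulling
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to extract force-dependent unfolding and folding kinetic
    rates from optical-tweezers pulling experiments on two-state
    biomolecules, fit them with the Bell-Evans model, and map
    transition-state distances into amino-acid units with worm-like-chain
    and freely-jointed-chain elasticity. Includes force-distance-curve
    event detection (median filtering, folded-baseline fitting, Bayesian
    state classification), survival-probability rate extraction from
    rupture-force distributions, dwell-time analysis of equilibrium
    hopping traces, a reproducible synthetic-data generator for two-state
    pulling and hopping experiments, and force-dependent transition-state
    profiles (monomers to the barrier, mechanical fragility) that quantify
    Leffler-Hammond movement of the transition state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
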