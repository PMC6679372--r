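Package: alchemr
Title: Alchemical Free-Energy Estimators and Thermodynamic-Cycle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of alchemical free-energy calculations of
    relative ligand-binding affinities: thermodynamic integration over a
    lambda-coupling schedule, one-step (Zwanzig) perturbation for charge
    redistribution on a simulated ensemble, block-averaging error estimation
    for correlated time series, hysteresis and cycle-closure diagnostics,
    assembly of relative binding free energies from bound and unbound legs of
    a thermodynamic cycle, energy-entropy decomposition of ligand-surrounding
    interactions, and sensitivity statistics of computed affinities against
    experimental values with censored lower bounds. Includes a seeded
    Metropolis Monte Carlo generator of lambda-coupled toy ensembles with
    closed-form free energies for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
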