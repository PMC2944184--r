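Package: divtempo
Title: Diversification Tempo Inference from Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether a clade radiated in an early burst or
    diversified at a constant rate, built around ultrametric chronograms.
    Implements lineage-through-time curves and the Pybus-Harvey gamma
    statistic with its one-tailed constant-rates test, Monte-Carlo
    constant-rates (MCCR) testing that corrects for incomplete and
    taxonomically uncertain sampling via simulated-then-pruned pure-birth
    null trees, a serial node-truncation profile of gamma, maximum-likelihood
    fitting of five diversification models (pure-birth, birth-death,
    density-dependent exponential and logistic, Yule-2-rate) with a
    simulation-calibrated delta-AIC decision rule, and symmetric two-state
    (Mk1) ancestral-area reconstruction with focal-root determination. A
    seeded simulator for pure-birth and birth-death chronograms with random
    incomplete sampling and Mk1 tip characters drives the null
    distributions, calibrations and end-to-end demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
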