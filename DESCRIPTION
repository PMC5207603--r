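Package: fuzzyflock
Title: Evolving Collective Prey Behaviour with Linguistic Fuzzy Rule-Based Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An artificial-life model of predator-prey dynamics in which prey
    agents are steered by evolvable linguistic (Mamdani) fuzzy rule-based
    systems. Provides the fuzzy inference engine (triangular and periodic
    triangular membership functions, product t-norm, probabilistic-sum
    aggregation, centre-of-gravity defuzzification), a 2D world with four
    predator attack tactics and an energy economy, open-ended steady-state
    evolution of variable-length rule bases (Pittsburgh coding), order
    parameters for collective motion (polarization, rotation, group
    detection, swarm/mill/polar state classification), rule-base summary
    statistics, and scripted scene generators for testing. The simulation
    core is written in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
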