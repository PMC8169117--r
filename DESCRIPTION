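Package: seedswitch
Title: Stochastic ABA-GA Bistable Switch Model of Seed Germination Timing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a minimal stochastic model of the
    abscisic acid (ABA) - gibberellic acid (GA) hormone network that controls
    the timing of seed germination. The network couples ABA, GA and a lumped
    germination inhibitor ("Integrator") through Hill-type regulatory
    functions and behaves as a bistable switch; chemical Langevin dynamics
    integrated with the stochastic Heun method generate per-seed germination
    times. The package provides deterministic fixed-point and regime
    analysis (monostable/bistable/tristable classification), first-passage
    germination-time ensembles, trait statistics (coefficient of variation,
    mode, percentage germination) with the plate-level filters used for
    experimental day-binned counts, 1D/2D parameter scans, exogenous hormone
    dose-response experiments, and a generator of synthetic day-binned
    germination count tables emulating multiparent (MAGIC-style) line data.
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
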