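Package: desperation
Title: Desperation Thresholds, Toughness Signals and Community Violence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic-dynamic-programming model of individual decisions
    between exploitation (property crime), violence (a costly toughness
    signal) and submission, driven by a desperation threshold on an
    autocorrelated resource state, embedded in an agent-based population
    simulation. Provides mean-field encounter distributions, backward
    induction over a discretized resource grid, asynchronous strategy
    updating to equilibrium, and experiment drivers for policy maps,
    hysteresis sweeps, vector fields and violence-incentive curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
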