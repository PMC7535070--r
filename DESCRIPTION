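Package: discrimdesign
Title: Optimal Discriminating Designs for Nonlinear Models via Hybrid
    Particle Swarm Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes optimal experimental designs for discriminating between
    two or more nonlinear regression models under normal, lognormal, gamma, or
    binomial error assumptions.  Implements T- and Kullback-Leibler optimality
    criteria, max-min efficiency criteria for three or more rivals, and
    standardized maximin T-optimality over a set of plausible true-model
    parameters.  Designs are found by hybrid particle-swarm / quasi-Newton
    searches (PSO-QN, PSO-S-QN, Nested-PSO-QN), certified by the equivalence
    theorem, and benchmarked against Fedorov-Wynn and Remes exchange
    algorithms.  Ships classical dose-response, pharmacokinetic and
    polynomial discrimination problems as ready-made fixtures, an efficiency
    evaluator for candidate designs, and a config-driven command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
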