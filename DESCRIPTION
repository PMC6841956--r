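Package: pggbias
Title: Actor-Critic Learning and the Evolution of Cognitive Bias in Public
    Goods Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models groups of individuals that learn how much to invest into a
    joint project through actor-critic reinforcement learning, and the
    evolution of a heritable cognitive bias in the perceived cost of
    investing. Provides the quadratic-payoff public goods stage game, the
    one-state Gaussian-policy actor-critic learning dynamics, closed-form and
    iterative solvers for the one-shot Nash equilibrium, the selection
    gradient on perceived quality and the evolutionarily stable bias line,
    and an individual-based simulation of diploid populations under
    mutation, selection and drift.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
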