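Package: linkdyn
Title: Coevolution of Cooperation and Network Structure via Stochastic
    Linking Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulator and analytic toolkit for the coevolution
    of strategies and social ties in the Prisoner's Dilemma on a dynamical
    network with a constant number of links. Links are selected at random
    and break with a probability that depends on the strategies of their
    endpoints; broken links are rewired to random non-neighbors. Strategies
    evolve by pairwise-comparison (Fermi) imitation. The package provides
    the 3-state Markov chain over link types, its closed-form stationary
    distribution, stationary-link-weighted mean payoffs, the induced
    transformed game, the interior (unstable) equilibrium and the simple
    rule for stable cooperation, together with a fast C++ event-level
    simulator, experiment harnesses for basin-of-attraction curves and
    phase diagrams, mean-field (replicator/Langevin) dynamics, and
    readers/writers for edge lists, GraphML, CSV and JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
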