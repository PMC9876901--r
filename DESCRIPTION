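Package: travdyn
Title: Evolutionary and Learning Dynamics for the Traveler's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cooperation emerges in the Traveler's Dilemma,
    a two-player game in which each player claims an integer between a lower
    and an upper bound and the lower claimant is rewarded. The package builds
    the game's payoff structure and its decomposition into local Prisoner's
    Dilemma and global coordination sub-games, and implements three dynamics
    over the claim space: the replicator-mutator ordinary differential
    equations for an infinite population, a Wright-Fisher process with
    selection, bounded mutation and drift for a finite population, and
    two-player introspection dynamics with Fermi acceptance, including exact
    stationary distributions of the resulting Markov chain. Parameter sweeps,
    phase-boundary detection and boundary-curve fitting map the phase
    diagrams that separate convergence to the Nash equilibrium from
    convergence to cooperative high claims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
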