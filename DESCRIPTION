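Package: fitscape
Title: Adaptive Walks of a Regulator-Target Network on Discrete Fitness
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates evolutionary movement of the simplest transcription
    network (one signal-activated regulator, one target protein) on a
    discretized six-parameter fitness landscape. Each biochemical parameter
    takes one of 1000 discrete levels; a Gaussian-kernel mutational neighbor
    network of tunable per-parameter connectivity K defines which levels are
    reachable by a single mutation. Fitness is a cost-benefit function of the
    network's analytic steady state. Greedy adaptive walks (uniform choice
    among strictly beneficial one-mutant neighbors) are run to local or
    global optima, and ensemble drivers compute the critical-connectivity
    transition in the probability of reaching the global peak, steps to
    peak, speed of evolution, and between-trajectory variance dynamics.
    Includes exhaustively enumerable toy landscapes with an absorbing
    Markov-chain oracle for exact reach probabilities and expected step
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
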