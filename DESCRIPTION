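Package: skillscape
Title: Copying and Collaboration in Networked Collective Problem Solving
Version: 0.1.0
Authors@R:
    person("skillscape", "developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of groups searching rugged payoff
    landscapes. Skill-typed agents hill-climb on a two-dimensional solution
    grid and use an unweighted social network either to copy the solutions
    their neighbors currently occupy or to collaborate, borrowing their
    neighbors' perceptual skills to evaluate otherwise invisible cells.
    Includes generators for signal-plus-Perlin-noise landscapes and simple
    unimodal landscapes, path/complete/randomly-densified interaction
    networks, group outcome metrics (best, average, minimum payoff, Gini
    coefficient), and a Monte-Carlo experiment harness with a command-line
    interface for collaboration-frequency sweeps, network-density sweeps and
    collaborate-then-copy phase schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
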