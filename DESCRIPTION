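Package: visflock
Title: Vision-Based Flocking with Learned Collision Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of vision-based collective motion with
    collision avoidance on a toroidal plane, together with an
    evolution-learning training loop: a tabular stochastic Q-policy over discretised
    retinal observations (subtended angle, angular position and their time
    derivatives), trained by a genetic-algorithm action planner and steered
    by KNN-guided adaptive sampling of the state space. Includes swarm order
    and collision-rate metrics, random-walk and alignment-only baselines,
    parameter sensitivity sweeps, and tree-ensemble surrogate analysis of
    the learned policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ranger,
    randomForest,
    optparse
Config/testthat/edition: 3
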