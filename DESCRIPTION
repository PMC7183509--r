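Package: cogswarm
Title: Cognitive Swarming with Attractor Dynamics and Oscillatory Hebbian
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for hippocampally inspired swarming control in which
    inter-agent distances are mapped through spatial kernels to synaptic
    weights, modified by an oscillatory Oja-rule Hebbian learning step, and
    inverted back into desired distances that drive motion.  Provides
    polygonal 2-D environments with line-of-sight visibility and parametric
    generators (a fragmented multi-reward arena and a hairpin maze),
    multi-agent and single-entity ("cognitive swarm") simulation modes,
    reward capture, seeded parameter sweeps, and metrics for emergent
    structure (phase synchrony, reward-centered phase rings, capture
    statistics, spatial coverage, visibility clusters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
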