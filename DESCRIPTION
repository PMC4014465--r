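Package: swarmattn
Title: Attention-Field Swarm Dynamics, Spatial Order and the Selfish Herd
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of swarms in which every individual moves
    toward (or away from) the nearest neighbour found inside a limited angular
    attention field, seeking an ideal inter-individual distance. Provides the
    asynchronous movement rule with stress-zone stopping, direction noise and
    quasi-stationary-state detection; Voronoi-based order metrics (topological
    neighbour graph, sixfold bond-orientational order parameter, translational
    order parameter, domain-of-danger areas, cluster decomposition); scripted,
    seeded replicate experiments (attention-angle sweeps, convergence-time
    versus speed, noise-induced order-disorder transition, selfish-herd
    scenario); and analytic lattice fixtures with CSV trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    deldir,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
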