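Package: reconrings
Title: Simulation and Topological Analysis of Confined Reconnecting Ring Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin dynamics of confined bead-spring ring polymers that
    undergo bond-swap reconnection moves ("living" rings), together with the
    topological machinery needed to study their gelation: Gauss linking
    numbers, link networks and their clusters, knot detection by the
    Alexander determinant, a mean-field free-energy theory predicting ring
    number and the gelation point from the overlap concentration, and
    simulated elution (permeabilized-sphere escape) experiments. All
    simulations use reduced Lennard-Jones units with a Kremer-Grest type
    force field (WCA + FENE + Kratky-Porod bending) inside a repulsive
    spherical wall.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
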