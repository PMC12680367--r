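Package: fibranet
Title: Multiscale Force-Based Simulation of Cell-ECM Mechanical Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of the mechanical interplay between
    contractile cells and a crosslinked extracellular-matrix (ECM) fibre
    network.  The ECM is a random Voronoi network of bilinear elastic
    fibres, cells are polygonal agents built from Kelvin-Voigt segments
    with angular restoring forces and active myosin-driven contraction,
    and cell-ECM coupling is mediated by focal adhesions modelled as
    clusters of catch-bond integrins with mean-field binding kinetics.
    Includes a saddle-node bifurcation analysis of the reduced focal
    adhesion system, quantification metrics (local fibre orientation
    tensor and anisotropy, maximum-stress percolation paths with
    tortuosity), scripted parameter-sweep experiments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    igraph,
    deSolve,
    e1071,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
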