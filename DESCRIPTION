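Package: smlmclust
Title: Simulation and Bayesian Cluster Analysis of Single-Molecule
    Localization Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cluster analysis of single-molecule localization
    microscopy (SMLM) point patterns. Generates ground-truth clustered
    localization tables and blinking-fluorophore emulations, merges repeated
    detections of one fluorophore by spatio-temporal grouping, enumerates
    cluster proposals from three algorithms (Ripley's-K-based thresholding,
    DBSCAN, and persistence-based ToMATo) over a radius/threshold grid,
    scores every proposal under a Bayesian model with a Dirichlet-process
    partition prior that uses the per-localization precision, and derives
    cluster statistics (counts, convex-hull areas, densities, relative
    density, cumulative area distributions, Kruskal-Wallis group
    comparison). All artifacts of one run are kept in a single HDF5 store.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    data.table,
    yaml,
    parallel,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
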