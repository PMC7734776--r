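Package: loopstates
Title: Conformational State Analysis of Protein Loop Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis pipeline for quantifying the conformational
    states of a flexible protein loop across binding states: least-squares
    (Kabsch) superposition with RMSF and RMSD descriptors, greedy
    neighbour-count (Daura/GROMOS) RMSD clustering with cross-system cluster
    composition, non-metric multidimensional scaling of cluster-centre
    distances with single-linkage meta-cluster grouping, geometric
    hydrogen-bond detection, and short-range Coulomb/Lennard-Jones
    interaction-energy accounting. Includes a synthetic multi-conformation
    trajectory generator with planted state occupancies so every stage is
    testable without external simulation data, plus multi-model PDB and
    plain-text topology sidecar input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
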