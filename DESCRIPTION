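Package: statefate
Title: Discrete Cell States, Lineage Trees and Threshold-Network Ensembles
    from Single-Cell UMI Counts
Version: 0.1.0
Authors@R:
    person("statefate", "developers", email = "statefate@example.org",
           role = c("aut", "cre"))
Description: Infers discrete cell states and their lineage tree from
    single-cell UMI count matrices by iterative Bayesian triplet analysis,
    binarizes the result into gene modules, samples an ensemble of
    threshold-network (Hopfield-like) coupling matrices that stabilize the
    observed states by linear programming with random hyperplane objectives,
    and produces ensemble predictions of state-dependent responses to
    overexpression and signalling perturbations.  A synthetic-data module
    generates planted lineage datasets and feasible binary state instances
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    Rtsne,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
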