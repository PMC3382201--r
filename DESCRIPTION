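Package: hierconn
Title: Hierarchical Analysis of Weighted Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analysis of multi-subject weighted
    structural connectomes: robust edge pruning by an iterative pooled-variance
    z-test, weighted node-degree distribution fitting and model comparison
    (normal, gamma, shifted exponential, Pareto with Clauset-style x_min
    selection), weighted clustering coefficients, shortest-path and
    small-world statistics against weight-shuffled null networks, self-tuning
    normalized-cuts hierarchical clustering with Givens-rotation eigenvector
    alignment and an SVD-based discretization cross-check, and inter-cluster
    connectivity decay along the recovered hierarchy tree. Includes a
    synthetic multi-subject connectome generator with a planted base-2
    hierarchy for benchmarking and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr
Config/testthat/edition: 3
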