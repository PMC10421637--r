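Package: spinbench
Title: Benchmarking Direct Coupling Analysis Against Local Correlation
    Thresholding on Spin Models over Random Graphs
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates ferromagnetic Ising and Potts models on Erdos-Renyi
    random graphs, draws exact (coupling-from-the-past) and Gibbs samples
    from their Boltzmann distributions across the order-disorder phase
    transition, and benchmarks global network reconstruction by naive
    mean-field inversion (mean-field direct coupling analysis) against
    local correlation thresholding.  Includes closed-form mean-field
    theory (order parameters, critical temperatures, the mean-field
    f-divergence curve), ROC/AUC discriminability metrics, rms coupling
    error decompositions, shortest-path characterisation of false
    positives, and an importance-sampling estimator of f-divergences
    (Jensen-Shannon by default) between graphical models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
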