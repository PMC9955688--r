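Package: rbnhet
Title: Random Boolean Networks with Structural, Temporal, and Functional Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulator and measurement toolkit for random Boolean networks (RBNs)
    as models of gene regulatory networks. Generates network ensembles whose
    out-degree distribution (regular, Poisson, exponential), update schedule
    (synchronous, out-degree period, shared "ceil" period), and rule bias
    (point, Gaussian, uniform, triangular) can each be homogeneous or
    heterogeneous across nodes. Provides an entropy-based complexity measure
    used to locate critical (order-chaos) dynamics, a perturbation protocol with
    an associated fragility/antifragility statistic, and orchestration for
    complexity-versus-connectivity and fragility sweep experiments with
    replicate statistics, reproducible hierarchical seeding, and plain-text
    serialization of models, trajectories, and curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
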