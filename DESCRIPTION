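Package: spinedyn
Title: Stochastic Weight Dynamics in Clustered Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time stochastic simulation of synaptic weight dynamics
    in small clusters of dendritic spines. Each synapse receives competing
    daily potentiation (LTP) and depression (LTD) increments whose magnitude
    scales with the current weight and with a weight-dependent volatility
    factor; synapses in a cluster compete for limited plasticity resources,
    weak synapses are silenced, and silent synapses regenerate when an
    adjacent synapse is strong. The package provides the update equations, a
    compiled ensemble driver with reproducible seeding, scripted protocols
    (steady-state distribution, LTP-amplitude perturbation, memory imprint,
    weight decorrelation, cluster stability), and the accompanying statistics:
    log-spaced weight histograms, log-normal and normal fits, daily-change
    profiles, Pearson correlation series and exponential decay-time fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
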