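Package: queuenet
Title: Discrete-Event Queueing Dynamics on Directed Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models large-scale brain networks as discrete-event queueing
    systems in which signal units are generated by a Poisson process, diffuse
    over directed projections, queue in finite last-in-first-out buffers, and
    are absorbed at their destinations. Provides node-level communication
    metrics (arrivals, node contents, utilization), degree-preserving and
    direction-reversal null-model ensembles with z-score inference, traffic
    hot-spot and convergence-zone detection, phase-regime mapping of the
    steady/jammed transition, and generators for synthetic networks with
    planted funnel motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    withr,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
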