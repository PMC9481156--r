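Package: fatecoord
Title: Inferring Cell-Fate Coordination Rules from Spatiotemporal Cell Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and interpreting cell-fate decisions
    (division, delamination, persistence) in homeostatic epithelia from
    cell-tracking data. Cell tracks and cell-contact networks are assembled
    into spatiotemporal graphs (cells as nodes, contact edges within frames,
    lineage edges across frames, including division forks). A family of
    message-passing neural network models -- bidirectional, unidirectional,
    cell-external and contact-free variants with sum or mean neighbor
    aggregation -- is trained with a class-weighted cross-entropy loss and an
    auxiliary neutral-baseline loss, and interrogated with integrated-gradients
    attribution pooled over relative spatiotemporal positions, with a
    significance band derived from a deliberately uninformative random
    feature. An agent-based simulator of a homeostatic cell layer with paired
    stochastic division/delamination rules provides ground-truth data with
    implanted coordination rules, and a neighbor fate net-imbalance statistic
    offers an independent cross-check. All numerics (multilayer perceptrons,
    reverse-mode gradients, Adam, integrated gradients) are implemented in
    base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
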