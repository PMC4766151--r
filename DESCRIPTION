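Package: temponet
Title: Temporal Correlation and Topological Overlap for Contact Network Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much the edge configuration of a
    temporal network persists between consecutive snapshots. Implements the
    node-level topological overlap, the per-step average topological overlap
    under three normalisations (all nodes, maximal largest-component size,
    maximal active-node count), and the temporal correlation coefficient,
    together with analytic distortion ratios and bounds between the three
    normalisations. Includes time-window aggregation of time-stamped contact
    events (e.g. livestock movement records) into snapshot sequences,
    per-pair network covariates and descriptive-moment summaries, a
    convergence experiment, built-in worked example networks, and a seeded
    synthetic trade-event generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
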