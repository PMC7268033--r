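Package: temporalpc
Title: Participation Coefficients for Temporal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying nodal integration and segregation in
    weighted temporal networks, aimed at time-varying functional
    connectivity. Estimates per-time-point connectivity from multivariate
    signals (distance-weighted Pearson correlation and multiplication of
    temporal derivatives), detects per-slice modularity communities with
    Jaccard-based temporal consensus relabeling, and computes four
    participation-coefficient variants: the static participation
    coefficient, per-slice participation against a static partition (PC_S),
    per-slice participation against each slice's own temporal partition
    (PC_T), and the temporal participation coefficient (TPC), which
    evaluates every slice against all temporal partitions and averages so
    that values stay comparable across time. Auxiliary nodal measures
    (flexibility, within-module degree z-scores), divergence diagnostics
    between the variants, and synthetic generators with planted recurring
    community structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
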