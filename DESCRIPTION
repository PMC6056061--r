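Package: netsubgraph
Title: Subgraph Decomposition of Dynamic Signed Functional Networks
Version: 0.1.0
Authors@R:
    person("netsubgraph", "maintainers", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Decomposes signed, block-wise correlation networks into additive
    subgraphs via regularized non-negative matrix factorization (alternating
    non-negative least squares with block principal pivoting), characterizes
    subgraph topology (core-periphery structure against a node-to-system
    partition, with permutation nulls), tracks subgraph expression dynamics
    across tasks and demand conditions, links expression to behavioral
    performance (reaction-time cost), and assesses split-half test-retest
    reliability via optimal linear-assignment matching. Ships a synthetic
    cohort generator with planted low-rank signed covariance structure so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
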