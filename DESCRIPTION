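Package: stabilitycore
Title: Boolean Network Contextualization and Stability Cores from
    Expression and Promoter Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a cell-fate "stability core" from omics data.
    Implements threshold-based differential expression and promoter CpG
    methylation calling for a target lineage against two reference
    lineages, integration of demethylation with up-regulation, synchronous
    Boolean network dynamics with exhaustive attractor computation,
    Johnson enumeration of signed elementary circuits, and evolutionary
    (estimation-of-distribution) pruning of a prior signed regulatory
    network toward a subnetwork whose attractors contain two observed
    stable cell states. The stability core is extracted as the nontrivial
    strongly connected components of the contextualized network.
    Includes seeded synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
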