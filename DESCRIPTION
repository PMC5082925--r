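Package: cldnet
Title: Network Analysis of Causal Loop Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the structure of community-built causal loop
    diagrams (systems maps) by treating them as directed unweighted
    networks. Reads variable keys and edge lists from delimited text,
    computes global topology summaries (density, degree distributions,
    average directed path length, diameter, isolates), node centrality
    (in-degree, out-degree, Brandes betweenness) with leverage-point
    rankings, multilevel greedy (Louvain-style) community detection with
    modularity scoring, bounded feedback-loop enumeration, and comparison
    of an observed diagram against seeded uniform random baselines to
    flag small-world-like and heavy-tailed degree structure. Includes
    seeded generators of CLD-like synthetic networks so every stage of
    the pipeline is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
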