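Package: kgradiate
Title: Radiate Analysis and Influence Tracing on Pathway Knowledge Graphs
Version: 0.1.0
Authors@R: person("Pathway", "Graph Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Knowledge mining on Reactome-style pathway property graphs.
    Implements radiate analysis (forward and reverse personalized PageRank
    from a molecular source set), all-shortest-path and highest-influence
    path tracing with Sankey trace-graph export, currency-metabolite
    exclusion, Gene Ontology enrichment (one-sided Fisher exact test with
    Benjamini-Hochberg adjustment), dictionary-based entity recognition
    with entity clouds and iterative semantic expansion, plus a seeded
    synthetic pathway-graph generator so the complete workflow is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
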