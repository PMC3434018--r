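Package: procgraph
Title: Process Graphs of Inter-Dependent Function Nodes from Annotated
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a functionally annotated protein-protein interaction
    (PPI) network into a non-redundant process graph whose nodes are
    function nodes (sets of at least two interacting proteins sharing an
    annotation) and whose edges portray dependencies among functions.
    Redundant protein-to-function assignments are pruned with topological
    scores computed against k-cliques and clique-percolation communities:
    a protein membership score (PMS) decides which function node best
    explains each protein, and a node topological score (NTS) ranks
    function nodes by their overlap with protein clusters so the graph can
    be reduced to its best supported part. Includes readers for OBO
    ontologies, GAF/TSV annotations and BioGRID-style interaction tables,
    canonical GraphML/SIF/DOT/TSV exporters, a synthetic generator of
    annotated networks with planted functional modules for benchmarking,
    and enumeration of open three-node paths as testable causal
    hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
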