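Package: litnet
Title: Co-Occurrence Networks and Hierarchies of Bioentities from Annotated Literature
Version: 0.1.0
Authors@R:
    person("litnet", "developers", email = "litnet@localhost", role = c("aut", "cre"))
Description: Tools for mining bioentity co-occurrence from PubTator-format
    literature annotations entirely offline. Parses annotated abstracts,
    normalizes raw annotation identifiers to typed entity identifiers (NCBI
    TaxID, MeSH UI), evaluates Boolean keyword queries (AND/OR/NOT, quoted
    phrases, trailing-asterisk truncation) against a local corpus, builds
    weighted co-occurrence networks with per-edge document provenance,
    re-organizes hits into NCBI-taxonomy induced subtrees and MeSH
    tree-number forests, combines networks with set operations, scores
    network similarity by common nodes, recommends allied species from a
    reference species list, and exports Gephi-compatible GEXF/GraphML.
    Includes a seeded fixture generator so the whole pipeline is testable
    without any download, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
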