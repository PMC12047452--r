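Package: stpath
Title: Signal Transduction Pathway Encoding, Alignment and Key-Factor Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for working with signal transduction pathways encoded
    under the hierarchical four-level ST classification system. Parses and
    validates ST codes against the embedded location/action taxonomy, scores
    code pairs by longest-common-prefix similarity, aligns coded pathways with
    a zero-gap-penalty dynamic program normalized by the longer pathway length,
    merges pathway sets into directed weighted networks with category-annotated
    edges (GraphML and JSON node-link export), and ranks network nodes by a
    damped weighted PageRank iteration for key-factor identification. Includes
    a deterministic synthetic generator for interaction catalogs and pathways
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
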