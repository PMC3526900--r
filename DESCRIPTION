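Package: trispec
Title: Species Trees from Event-Labeled Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deriving species trees from gene trees whose interior
    vertices are labeled as speciation or duplication events. Extracts the
    speciation-rooted triples on pairwise distinct species that constrain the
    species tree, decides species-tree existence by rooted-triple consistency
    using the BUILD (Aho) algorithm, constructs and validates reconciliation
    maps from gene-tree vertices to species-tree vertices and edges, and
    includes a duplication-loss simulator over ultrametric age-model species
    trees together with a split-recovery experiment that quantifies how much
    species-tree information event-labeled gene trees carry.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
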