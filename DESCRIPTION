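Package: coexmod
Title: Weighted Gene Co-Expression Modules for Stress Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted gene co-expression networks from multi-tissue,
    multi-stage expression designs and annotates uncharacterized genes
    through network context. Implements soft-thresholded correlation
    adjacency with the topological overlap measure, hierarchical module
    detection with a static-plus-secondary tree cut, permutation-based
    module quality statistics (Zsummary/psummary), mutual-information and
    approximate maximal-information-coefficient networks scored by the
    context likelihood of relatedness, Markov clustering, tissue- and
    stage-wise differential expression mapped onto modules, hub-based
    candidate selection, ortholog-bridged conserved-neighborhood annotation
    transfer, guide-gene subnetworks, cross-method consensus, and IUPAC
    cis-element scanning of promoter sequences. A seeded synthetic-data
    generator with serialized ground truth makes the whole workflow
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
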