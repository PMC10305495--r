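Package: dtnet
Title: Protein-Drug Network Construction and Off-Target Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds heterogeneous protein-drug interaction networks from a
    drug-target table and a binary protein-protein interactome, extracts
    first-neighbor off-target candidate sets, computes network topology
    (degree, betweenness, closeness, diameter/radius), compares drug
    neighborhoods with the Jaccard index and drug structures with the
    Tanimoto coefficient on path-based fingerprints, runs term-for-term
    Gene Ontology over-representation statistics (hypergeometric and
    Fisher exact tests with Benjamini-Hochberg FDR), and profiles
    proteoform events and gene-disease associations for targets and their
    interactors. Includes seeded synthetic-data generators that emulate
    drug-target, interactome, annotation, disease and proteoform
    snapshots with known ground truth, so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
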