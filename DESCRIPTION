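Package: kbgraph
Title: Property-Graph Storage and Traversal Queries for Frame-Based
    Pathway Knowledgebases
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for migrating a frame-based biological pathway
    knowledgebase (classes with typed slots, instances holding primitive
    values or references) from a relational table layout into an embedded
    labelled property graph, and for querying the result by graph
    traversal. Provides a built-in Reactome-style pathway schema
    (pathways containing reaction-like events whose participants are
    physical entities, including nested complexes and entity sets), a
    depth-first visit-once importer, pathway-participant and
    entity-to-pathway queries, complex/set decomposition, post-migration
    integrity verification between the two representations, a seeded
    synthetic-knowledgebase generator with machine-readable ground truth,
    and a desk-scale benchmark harness comparing join-style relational
    access with graph traversal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    parallel
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
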