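Package: kgbuildr
Title: Desk-Scale Construction, Canonicalization and Querying of Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a semantically standardized biomedical knowledge
    graph from heterogeneous knowledge sources at desk scale. Provides ordered
    multi-format source ingestion (constrained-subset ontology TTL and RDF/XML,
    triple TSV, record-oriented XML/JSON) into a common graph schema, a
    Biolink-style semantic layer (category and predicate hierarchies, inverse-pair
    orientation, relation normalization, identifier-prefix priorities),
    provenance-preserving edge coalescing, connected-component concept
    canonicalization with canonical-identifier election, QC build reports with
    cross-build drift flagging, degree statistics with discrete power-law fitting,
    meta-triple tabulation, an in-memory one-hop query engine, a synthetic
    knowledge-source suite generator with exact ground-truth manifests, and a
    checksum-aware staged build runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    xml2,
    pracma,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
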