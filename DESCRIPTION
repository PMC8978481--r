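Package: aopwikirdf
Title: Convert AOP-Wiki XML Dumps into Semantic-Web RDF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses AOP-Wiki-style XML dumps of adverse outcome pathways
    (AOPs) into a typed knowledge model, enriches key events and key event
    relationships with HGNC gene identifiers by dictionary text matching,
    maps PRotein Ontology biological objects and chemical CAS registry
    numbers to external database identifiers through a pluggable
    (static-table or BridgeDb-style HTTP) cross-reference backend, and
    emits three schema-conformant Turtle files: the main knowledge graph,
    a text-mapped gene graph, and VoID dataset metadata. Includes Turtle
    validation, graph statistics, a SPARQL query catalog, and a seeded
    synthetic-fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
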