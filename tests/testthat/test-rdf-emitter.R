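test_that("a fully populated AOP carries all 26 schema predicates", {
  cc <- canonical_conversion()
  df <- cc$conv$main$triples
  preds <- unique(df$predicate[df$subject == "https://identifiers.org/aop/38"])
  expect_length(preds, 26L)
  expect_setequal(compact_iri(preds),
                  sub("^rdf:type$", "rdf:type", schema_for("aop")$predicate))
})

test_that("a minimal AOP emits only the mandatory triples", {
  path <- write_xml_fixture('<aop id="9"><title>Bare</title></aop>')
  model <- parse_aopwiki_xml(path)
  t <- emit_aop(model$aops[["9"]], model)
  expect_setequal(compact_iri(unique(t$predicate)),
                  c("rdf:type", "dc:identifier", "rdfs:label", "dc:title",
                    "foaf:page", "dc:source"))
})

test_that("key event emission follows the published KE property table", {
  cc <- canonical_conversion()
  g <- cc$conv$main
  ke <- "https://identifiers.org/aop.events/1502"
  expect_true(has_triple(g, ke, "a", resolve_curie("aopo:KeyEvent")))
  expect_true(has_triple(g, ke, "dc:title", "Histone deacetylase inhibition",
                         "literal"))
  expect_true(has_triple(g, ke, "aopo:CellTypeContext",
                         resolve_curie("cl:0000000")))
  expect_true(has_triple(g, ke, "aopo:OrganContext",
                         resolve_curie("uberon:0000062")))
  expect_true(has_triple(g, ke, "go:0008150", resolve_curie("go:0004857")))
  expect_true(has_triple(g, ke, "pato:0001241", resolve_curie("pr:000008478")))
  # free-text biological actions and taxa are plain literals
  expect_true(has_triple(g, ke, "pato:0000001", "WIKI:2", "literal"))
  expect_true(has_triple(g, ke, "ncbitaxon:131567", "WCS_9606", "literal"))
  expect_true(has_triple(g, ke, "ncbitaxon:131567",
                         resolve_curie("ncbitaxon:10116")))
  expect_true(has_triple(g, ke, "dcterms:isPartOf",
                         resolve_curie("aop:212")))
  # a KE without a measurement method gets no measurement triple
  ke55 <- "https://identifiers.org/aop.events/55"
  df <- g$triples
  expect_false(resolve_curie("mmo:0000000") %in%
                 df$predicate[df$subject == ke55])
})

test_that("a KE belonging to several AOPs gets one isPartOf per parent", {
  path <- write_xml_fixture(c(
    '<aop id="1"><title>A</title><key-events><key-event id="7"/></key-events></aop>',
    '<aop id="2"><title>B</title><key-events><key-event id="7"/></key-events></aop>',
    '<aop id="3"><title>C</title><key-events><key-event id="7"/></key-events></aop>',
    '<key-event id="7"><title>K</title></key-event>'))
  model <- parse_aopwiki_xml(path)
  t <- emit_ke(model$kes[["7"]], model)
  expect_equal(sum(t$predicate == resolve_curie("dcterms:isPartOf")), 3L)
})

test_that("KER emission links upstream and downstream key events", {
  cc <- canonical_conversion()
  g <- cc$conv$main
  ker <- "https://identifiers.org/aop.relationships/865"
  expect_true(has_triple(g, ker, "a", resolve_curie("aopo:KeyEventRelationship")))
  expect_true(has_triple(g, ker, "aopo:has_upstream_key_event",
                         "https://identifiers.org/aop.events/844"))
  expect_true(has_triple(g, ker, "aopo:has_downstream_key_event",
                         "https://identifiers.org/aop.events/845"))
  expect_true(has_triple(g, ker, "dcterms:created", "2016-11-29T18:41:35",
                         "typed"))
  expect_true(has_triple(g, ker, "dcterms:isPartOf",
                         resolve_curie("aop:131")))
})

test_that("stressor emission links chemicals and all referencing parents", {
  cc <- canonical_conversion()
  g <- cc$conv$main
  s208 <- "https://identifiers.org/aop.stressor/208"
  expect_true(has_triple(g, s208, "a", resolve_curie("nci:C54571")))
  expect_true(has_triple(g, s208, "aopo:has_chemical_entity",
                         "https://identifiers.org/cas/25812-30-0"))
  # referenced by AOP 131 and KE 844
  df <- g$triples
  parents <- df$object[df$subject == s208 &
                         df$predicate == resolve_curie("dcterms:isPartOf")]
  expect_setequal(parents, c("https://identifiers.org/aop/131",
                             "https://identifiers.org/aop.events/844"))
  # a stressor without chemicals emits no chemical triple
  s9 <- "https://identifiers.org/aop.stressor/9"
  expect_false(resolve_curie("aopo:has_chemical_entity") %in%
                 df$predicate[df$subject == s9])
})

test_that("chemical emission carries both chemical types and typed identifier nodes", {
  cc <- canonical_conversion()
  g <- cc$conv$main
  chem <- "https://identifiers.org/cas/103-90-2"
  expect_true(has_triple(g, chem, "a", resolve_curie("cheminf:000000")))
  expect_true(has_triple(g, chem, "a", resolve_curie("cheminf:000446")))
  expect_true(has_triple(g, chem, "cheminf:000446", "103-90-2", "literal"))
  expect_true(has_triple(g, chem, "dc:title", "Acetaminophen", "literal"))
  expect_true(has_triple(g, chem, "dcterms:alternative", "Paracetamol",
                         "literal"))
  inchikey <- "https://identifiers.org/inchikey/RZVAJINKPMORJF-UHFFFAOYSA-N"
  expect_true(has_triple(g, chem, "cheminf:000059", inchikey))
  expect_true(has_triple(g, inchikey, "a", resolve_curie("cheminf:000059")))
  expect_true(has_triple(g, chem, "skos:exactMatch",
                         "https://identifiers.org/chebi/46195"))
  expect_true(has_triple(g, "https://identifiers.org/chebi/46195", "a",
                         resolve_curie("cheminf:000407")))
  expect_true(has_triple(g, chem, "dcterms:isPartOf",
                         "https://identifiers.org/aop.stressor/57"))
  # without xrefs there is no exactMatch
  t <- emit_chemical(cc$model$chemicals[["103-90-2"]], cc$model, xrefs = NULL)
  expect_false(resolve_curie("skos:exactMatch") %in% t$predicate)
})

test_that("PR-annotated biological objects gain exactMatch links in the main graph", {
  cc <- canonical_conversion()
  g <- cc$conv$main
  pr <- resolve_curie("pr:000016890")
  expect_true(has_triple(g, pr, "a", resolve_curie("pato:0001241")))
  expect_true(has_triple(g, pr, "skos:exactMatch",
                         "https://identifiers.org/uniprot/P06132"))
  expect_true(has_triple(g, "https://identifiers.org/uniprot/P06132", "a",
                         resolve_curie("edam:data_2291")))
})

test_that("the gene graph links text-mapped entities to typed HGNC subjects", {
  cc <- canonical_conversion()
  g <- cc$conv$genes
  urod <- "https://identifiers.org/hgnc/UROD"
  expect_true(has_triple(g, "https://identifiers.org/aop.relationships/865",
                         "edam:data_1025", urod))
  expect_true(has_triple(g, urod, "a", resolve_curie("edam:data_2298")))
  em <- g$triples[g$triples$subject == urod &
                    g$triples$predicate == resolve_curie("skos:exactMatch"), ]
  expect_equal(nrow(em), 3L)
  # no matches -> empty graph
  empty <- emit_gene_graph(cc$conv$matches[0, ], NULL)
  expect_equal(graph_size(empty), 0L)
})

test_that("VoID metadata is self-consistent and covers both datasets", {
  cc <- canonical_conversion()
  void <- cc$conv$void$triples
  ds <- void$subject[void$predicate == RDF_TYPE_IRI &
                       void$object == resolve_curie("void:Dataset")]
  expect_length(ds, 2L)
  tri <- void[void$predicate == resolve_curie("void:triples") &
                void$subject %in% ds, ]
  sizes <- as.integer(tri$object[order(tri$subject)])
  expect_setequal(sizes, c(graph_size(cc$conv$main), graph_size(cc$conv$genes)))
  lic <- void[void$predicate == resolve_curie("dcterms:license"), ]
  expect_true(all(lic$object == "https://creativecommons.org/licenses/by/4.0/"))
  # license passes through configuration
  v2 <- emit_void(cc$conv$main, cc$conv$genes,
                  list(license = "https://example.org/license"))
  expect_true(any(v2$triples$object == "https://example.org/license"))
})

test_that("every internally linked object is a typed subject (referential closure)", {
  cc <- canonical_conversion()
  for (g in list(cc$conv$main, graph_union(cc$conv$main, cc$conv$genes))) {
    df <- g$triples
    internal <- !is.na(iri_prefix(df$object)) &
      iri_prefix(df$object) %in% c("aop", "aop.events", "aop.relationships",
                                   "aop.stressor") & df$kind == "iri"
    linked <- unique(df$object[internal])
    typed_subjects <- unique(df$subject[df$predicate == RDF_TYPE_IRI])
    expect_true(all(linked %in% typed_subjects))
  }
})

test_that("MIE and AO objects are subsets of each AOP's key events", {
  cc <- canonical_conversion()
  df <- cc$conv$main$triples
  for (aop in unique(df$subject[df$object ==
                                  resolve_curie("aopo:AdverseOutcomePathway")])) {
    kes <- df$object[df$subject == aop &
                       df$predicate == resolve_curie("aopo:has_key_event")]
    mies <- df$object[df$subject == aop &
                        df$predicate ==
                          resolve_curie("aopo:has_molecular_initiating_event")]
    aos <- df$object[df$subject == aop &
                       df$predicate ==
                         resolve_curie("aopo:has_adverse_outcome")]
    expect_true(all(mies %in% kes))
    expect_true(all(aos %in% kes))
  }
})

test_that("type totals equal model collection sizes and predicates stay in-schema", {
  cc <- canonical_conversion()
  df <- cc$conv$main$triples
  count_type <- function(cl) {
    length(unique(df$subject[df$predicate == RDF_TYPE_IRI &
                               df$object == resolve_curie(cl)]))
  }
  expect_equal(count_type("aopo:AdverseOutcomePathway"), length(cc$model$aops))
  expect_equal(count_type("aopo:KeyEvent"), length(cc$model$kes))
  expect_equal(count_type("aopo:KeyEventRelationship"), length(cc$model$kers))
  # main-graph predicate vocabulary is a subset of the schema slices
  allowed <- resolve_curie(unique(predicate_schema()$predicate))
  expect_true(all(unique(df$predicate) %in% allowed))
  # no duplicate triples survive serialization
  key <- paste(df$subject, df$predicate, df$object, df$kind)
  expect_false(anyDuplicated(key) > 0)
})
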