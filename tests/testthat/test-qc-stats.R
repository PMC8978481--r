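written_canonical <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- tempfile()
      cache <<- write_rdf_files(canonical_conversion()$conv, dir)
    }
    cache
  }
})

test_that("generated output validates with zero errors", {
  rep <- validate_files(written_canonical())
  expect_true(rep$syntax_ok)
  expect_length(rep$datatype_errors, 0L)
  expect_length(rep$dangling_links, 0L)
})

test_that("corrupted files are caught per error class", {
  paths <- written_canonical()
  # datatype corruption: break a dateTime lexical form
  bad_dt <- tempfile(fileext = ".ttl")
  txt <- readLines(paths[["main"]])
  txt <- sub("2016-11-29T18:41:16", "2016-11-29 18:41:16", txt, fixed = TRUE)
  writeLines(txt, bad_dt)
  rep <- validate_files(bad_dt)
  expect_true(rep$syntax_ok)
  expect_length(rep$datatype_errors, 1L)
  # syntax corruption: truncate mid-statement
  bad_syn <- tempfile(fileext = ".ttl")
  writeLines(head(readLines(paths[["main"]]), 60L), bad_syn)
  rep2 <- validate_files(bad_syn)
  expect_false(rep2$syntax_ok)
  expect_gte(length(rep2$syntax_errors), 1L)
  # dangling link: an entity IRI referenced but never defined
  bad_link <- tempfile(fileext = ".ttl")
  writeLines(c("@prefix aopo: <http://aopkb.org/aop_ontology#> .",
               "@prefix aop.events: <https://identifiers.org/aop.events/> .",
               "<https://identifiers.org/aop/1> aopo:has_key_event aop.events:999 ."),
             bad_link)
  rep3 <- validate_files(bad_link)
  expect_equal(rep3$dangling_links,
               "https://identifiers.org/aop.events/999")
  expect_error(validate_files(tempfile()), "not found")
})

test_that("stats totals are consistent with the graphs", {
  cc <- canonical_conversion()
  st <- compute_stats(cc$conv$main)
  df <- cc$conv$main$triples
  expect_equal(st$totals[["triples"]], nrow(df))
  expect_equal(st$totals[["subjects"]], length(unique(df$subject)))
  expect_equal(st$totals[["predicates"]], length(unique(df$predicate)))
  expect_equal(st$totals[["objects"]], length(unique(df$object)))
  expect_equal(sum(st$subject_type_counts[c("aopo:AdverseOutcomePathway",
                                            "aopo:KeyEvent",
                                            "aopo:KeyEventRelationship")]),
               with(cc$model, length(aops) + length(kes) + length(kers)))
  empty <- compute_stats(rdf_graph())
  expect_true(all(empty$totals == 0L))
  expect_length(empty$linkout_counts, 0L)
})

test_that("link-out counts partition exactMatch targets by database", {
  cc <- canonical_conversion()
  st <- compute_stats(list(cc$conv$main, cc$conv$genes))
  # brute-force oracle: count exactMatch rows whose target node is typed
  # with each database class
  df <- unique(rbind(cc$conv$main$triples, cc$conv$genes$triples))
  em <- df[df$predicate == resolve_curie("skos:exactMatch"), ]
  maps <- rbind(chemical_db_types()[c("token", "type_curie")],
                gene_db_types()[c("token", "type_curie")])
  want <- integer(0)
  for (i in seq_len(nrow(maps))) {
    typed <- df$subject[df$predicate == RDF_TYPE_IRI &
                          df$object == resolve_curie(maps$type_curie[i])]
    n <- sum(em$object %in% typed)
    if (n > 0L) want[[maps$token[i]]] <- n
  }
  expect_equal(as.list(st$linkout_counts), as.list(want[order(names(want))]))
  expect_equal(sum(st$linkout_counts),
               sum(df$predicate == resolve_curie("skos:exactMatch")))
})

test_that("the R statistics agree with SPARQL results from an independent engine", {
  paths <- written_canonical()
  st <- compute_stats(lapply(paths[c("main", "genes")], parse_turtle))
  n <- rdflib_query(paths[c("main", "genes")],
                    "SELECT (COUNT(*) AS ?n) WHERE { ?s ?p ?o }")
  expect_equal(as.integer(n$n), st$totals[["triples"]])
  cat_q <- query_catalog()
  types <- rdflib_query(paths[c("main", "genes")],
                        cat_q$sparql[cat_q$name == "subject_types"])
  got <- st$subject_type_counts
  expect_equal(length(got), nrow(types))
  expect_equal(unname(got[compact_iri(types$type)]), as.integer(types$n))
  links <- rdflib_query(paths[c("main", "genes")],
                        cat_q$sparql[cat_q$name == "linkouts_by_database"])
  expect_equal(sum(as.integer(links$n)), sum(st$linkout_counts))
})

test_that("every non-federated catalog query runs on the fixture graphs", {
  paths <- written_canonical()
  cat_q <- query_catalog()
  expect_gte(nrow(cat_q), 5L)
  for (i in which(!cat_q$network_required)) {
    expect_no_error(rdflib_query(paths, cat_q$sparql[i]))
  }
  fed <- cat_q[cat_q$category == "federated", ]
  expect_gte(nrow(fed), 1L)
  expect_true(all(grepl("SERVICE", fed$sparql)))
  expect_true(all(fed$network_required))
})
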