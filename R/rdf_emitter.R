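# Emit the enriched knowledge model as RDF: the main knowledge graph, the
# text-mapped gene graph, and VoID dataset metadata. All predicates and type
# annotations come from the declarative vocabulary tables; emitters contain
# no hard-coded IRIs.

cu <- function(x) resolve_curie(x)

# recycle0: zero ids must give zero IRIs, not a bare namespace IRI
iri_aop <- function(id) cu(paste0("aop:", id, recycle0 = TRUE))
iri_ke <- function(id) cu(paste0("aop.events:", id, recycle0 = TRUE))
iri_ker <- function(id) cu(paste0("aop.relationships:", id, recycle0 = TRUE))
iri_stressor <- function(id) cu(paste0("aop.stressor:", id, recycle0 = TRUE))
iri_cas <- function(cas) cu(paste0("cas:", cas, recycle0 = TRUE))
iri_hgnc <- function(symbol) cu(paste0("hgnc:", symbol, recycle0 = TRUE))

opt_lit <- function(subject, predicate_curie, value, datatype = NULL) {
  value <- value[!is.na(value) & nzchar(value)]
  if (!length(value)) return(empty_triples())
  if (is.null(datatype)) {
    triples(subject, cu(predicate_curie), value, "literal")
  } else {
    triples(subject, cu(predicate_curie), value, "typed", cu(datatype))
  }
}

link_to <- function(subject, predicate_curie, object_iris) {
  if (!length(object_iris)) return(empty_triples())
  triples(subject, cu(predicate_curie), object_iris, "iri")
}

# Resolve a list of term keys against the model; returns list(iris, literals)
term_objects <- function(keys, model) {
  iris <- character(0); lits <- character(0)
  for (k in keys) {
    term <- model$terms[[k]]
    if (is.null(term)) next
    if (!is.na(term$curie)) iris <- c(iris, cu(term$curie))
    else lits <- c(lits, term$free_text)
  }
  list(iris = iris, literals = lits)
}

entity_header <- function(subject, type_curie, label) {
  rbind(triples(subject, RDF_TYPE, cu(type_curie), "iri"),
        triples(subject, cu("dc:identifier"), subject, "iri"),
        triples(subject, cu("rdfs:label"), label, "literal"))
}

#' Emit the triples of one AOP
#'
#' One rdf:type triple, one triple per populated schema field (26 predicate
#' kinds when everything is filled), object IRIs for KE/KER/stressor links
#' (restricted to entities present in the model so the graph stays
#' referentially closed), a foaf:page link to the identifiers.org URL, and
#' `dc:source "AOPWiki"`.
#'
#' @param aop One AOP entry from an `aopwiki_model`.
#' @param model The model (for link resolution).
#' @return Data frame of triples.
#' @export
emit_aop <- function(aop, model) {
  s <- iri_aop(aop$id)
  rbind(
    entity_header(s, "aopo:AdverseOutcomePathway", paste("AOP", aop$id)),
    opt_lit(s, "dc:title", aop$title),
    opt_lit(s, "dcterms:alternative", aop$alternative_title),
    opt_lit(s, "dc:creator", aop$creators),
    opt_lit(s, "dcterms:abstract", aop$abstract),
    link_to(s, "nci:C54571",
            iri_stressor(intersect(aop$stressor_ids, names(model$stressors)))),
    link_to(s, "aopo:has_key_event",
            iri_ke(intersect(aop$ke_ids, names(model$kes)))),
    link_to(s, "aopo:has_molecular_initiating_event",
            iri_ke(intersect(aop$mie_ids, names(model$kes)))),
    link_to(s, "aopo:has_adverse_outcome",
            iri_ke(intersect(aop$ao_ids, names(model$kes)))),
    link_to(s, "aopo:has_key_event_relationship",
            iri_ker(intersect(aop$ker_ids, names(model$kers)))),
    opt_lit(s, "dc:description", aop$description),
    opt_lit(s, "pato:0000047", aop$sex_applicability),
    opt_lit(s, "aopo:LifeStageContext", aop$life_stage),
    opt_lit(s, "aopo:AopContext", aop$applicability_text),
    opt_lit(s, "edam:operation_3799", aop$quantitative_considerations),
    opt_lit(s, "aopo:has_evidence", aop$weight_of_evidence),
    opt_lit(s, "nci:C25725", aop$potential_applications),
    opt_lit(s, "nci:C25217", aop$overall_assessment),
    opt_lit(s, "nci:C48192", aop$ke_essentiality),
    opt_lit(s, "dc:accessRights", aop$status),
    triples(s, cu("foaf:page"), s, "iri"),
    opt_lit(s, "dcterms:created", aop$created, "xsd:dateTime"),
    opt_lit(s, "dcterms:modified", aop$modified, "xsd:dateTime"),
    opt_lit(s, "dc:source", "AOPWiki"))
}

# AOP ids a KE participates in, etc. (deterministic order)
parents_of <- function(model, field, id) {
  hits <- names(model$aops)[vapply(model$aops, function(a) id %in% a[[field]],
                                   logical(1))]
  hits[order(as.integer(hits))]
}

#' Emit the triples of one key event (main graph part)
#'
#' Biological level, measurement method, cell/organ context, KE component
#' (process/object/action) annotations, taxonomic applicability (IRIs for
#' ontology-backed terms, plain literals for free-text entries), stressor
#' links for molecular initiating events, and `dcterms:isPartOf` links to
#' parent AOPs. Text-mapped gene links live in the separate gene graph, see
#' [emit_gene_graph()].
#'
#' @param ke One key event entry.
#' @param model The model.
#' @return Data frame of triples.
#' @export
emit_ke <- function(ke, model) {
  s <- iri_ke(ke$id)
  cell <- term_objects(ke$cell_term[!is.na(ke$cell_term)], model)
  organ <- term_objects(ke$organ_term[!is.na(ke$organ_term)], model)
  process <- term_objects(ke$process_terms, model)
  object <- term_objects(ke$object_terms, model)
  action <- term_objects(ke$action_terms, model)
  taxa <- term_objects(ke$taxa, model)
  rbind(
    entity_header(s, "aopo:KeyEvent", paste("KE", ke$id)),
    opt_lit(s, "dc:title", ke$title),
    opt_lit(s, "dcterms:alternative", ke$alternative_title),
    opt_lit(s, "nci:C25664", ke$bio_level),
    opt_lit(s, "dc:description", ke$description),
    opt_lit(s, "mmo:0000000", ke$measurement_method),
    link_to(s, "nci:C54571",
            iri_stressor(intersect(ke$stressor_ids, names(model$stressors)))),
    link_to(s, "aopo:CellTypeContext", cell$iris),
    link_to(s, "aopo:OrganContext", organ$iris),
    link_to(s, "go:0008150", process$iris),
    link_to(s, "pato:0001241", object$iris),
    link_to(s, "pato:0000001", action$iris),
    opt_lit(s, "pato:0000001", action$literals),
    link_to(s, "ncbitaxon:131567", taxa$iris),
    opt_lit(s, "ncbitaxon:131567", taxa$literals),
    opt_lit(s, "pato:0000047", ke$sex_applicability),
    opt_lit(s, "aopo:LifeStageContext", ke$life_stage),
    triples(s, cu("foaf:page"), s, "iri"),
    link_to(s, "dcterms:isPartOf",
            iri_aop(parents_of(model, "ke_ids", as.character(ke$id)))),
    opt_lit(s, "dc:source", "AOPWiki"))
}

#' Emit the triples of one key event relationship (main graph part)
#'
#' Upstream/downstream key event links, evidence text (biological
#' plausibility, empirical support, uncertainties), taxonomic and sex/life
#' stage applicability, and `dcterms:isPartOf` to parent AOPs.
#'
#' @param ker One KER entry.
#' @param model The model.
#' @return Data frame of triples.
#' @export
emit_ker <- function(ker, model) {
  s <- iri_ker(ker$id)
  taxa <- term_objects(ker$taxa, model)
  rbind(
    entity_header(s, "aopo:KeyEventRelationship", paste("KER", ker$id)),
    link_to(s, "aopo:has_upstream_key_event",
            iri_ke(intersect(ker$upstream_ke, names(model$kes)))),
    link_to(s, "aopo:has_downstream_key_event",
            iri_ke(intersect(ker$downstream_ke, names(model$kes)))),
    opt_lit(s, "dc:description", ker$description),
    opt_lit(s, "nci:C80263", ker$biological_plausibility),
    opt_lit(s, "edam:data_2042", ker$empirical_support),
    opt_lit(s, "nci:C71478", ker$uncertainties),
    link_to(s, "ncbitaxon:131567", taxa$iris),
    opt_lit(s, "ncbitaxon:131567", taxa$literals),
    opt_lit(s, "pato:0000047", ker$sex_applicability),
    opt_lit(s, "aopo:LifeStageContext", ker$life_stage),
    triples(s, cu("foaf:page"), s, "iri"),
    opt_lit(s, "dcterms:created", ker$created, "xsd:dateTime"),
    opt_lit(s, "dcterms:modified", ker$modified, "xsd:dateTime"),
    link_to(s, "dcterms:isPartOf",
            iri_aop(parents_of(model, "ker_ids", as.character(ker$id)))))
}

#' Emit the triples of one stressor
#'
#' Chemical links via `aopo:has_chemical_entity` and `dcterms:isPartOf`
#' links to every AOP and key event that references the stressor.
#'
#' @param stressor One stressor entry.
#' @param model The model.
#' @return Data frame of triples.
#' @export
emit_stressor <- function(stressor, model) {
  s <- iri_stressor(stressor$id)
  id <- as.character(stressor$id)
  ke_parents <- names(model$kes)[vapply(model$kes, function(k)
    id %in% k$stressor_ids, logical(1))]
  ke_parents <- ke_parents[order(as.integer(ke_parents))]
  rbind(
    entity_header(s, "nci:C54571", paste("Stressor", stressor$id)),
    opt_lit(s, "dc:title", stressor$title),
    opt_lit(s, "dc:description", stressor$description),
    link_to(s, "aopo:has_chemical_entity",
            iri_cas(intersect(stressor$chemical_cas, names(model$chemicals)))),
    triples(s, cu("foaf:page"), s, "iri"),
    opt_lit(s, "dcterms:created", stressor$created, "xsd:dateTime"),
    opt_lit(s, "dcterms:modified", stressor$modified, "xsd:dateTime"),
    link_to(s, "dcterms:isPartOf",
            c(iri_ke(ke_parents),
              iri_aop(parents_of(model, "stressor_ids", id)))))
}

#' Emit the triples of one chemical
#'
#' The chemical node (a `cas:` IRI) is typed as both a chemical entity and a
#' CAS registry number, carries its CAS literal, name and synonyms, links to
#' its InChIKey and CompTox identifier nodes, and `skos:exactMatch` links to
#' every cross-referenced database identifier. Every linked identifier node
#' is typed with its database's CHEMINF class so link-outs can be counted
#' per database.
#'
#' @param chem One chemical entry.
#' @param model The model.
#' @param xrefs Cross-references for this chemical ([map_chemical()] result).
#' @return Data frame of triples.
#' @export
emit_chemical <- function(chem, model, xrefs = NULL) {
  s <- iri_cas(chem$cas)
  db_types <- chemical_db_types()
  type_of <- function(token) cu(db_types$type_curie[db_types$token == token])
  out <- rbind(
    triples(s, RDF_TYPE, cu(c("cheminf:000000", "cheminf:000446")), "iri"),
    triples(s, cu("dc:identifier"), s, "iri"),
    opt_lit(s, "cheminf:000446", chem$cas),
    opt_lit(s, "dc:title", chem$name),
    opt_lit(s, "dcterms:alternative", chem$synonyms))
  if (!is.na(chem$inchikey)) {
    node <- cu(paste0("inchikey:", chem$inchikey))
    out <- rbind(out,
                 triples(s, cu("cheminf:000059"), node, "iri"),
                 triples(node, RDF_TYPE, type_of("inchikey"), "iri"))
  }
  if (!is.na(chem$comptox) && nzchar(chem$comptox)) {
    node <- cu(paste0("comptox:", chem$comptox))
    out <- rbind(out,
                 triples(s, cu("cheminf:000568"), node, "iri"),
                 triples(node, RDF_TYPE, type_of("comptox"), "iri"))
  }
  if (!is.null(xrefs) && nrow(xrefs)) {
    targets <- cu(paste0(xrefs$target_db, ":", xrefs$target_id))
    out <- rbind(out,
                 triples(s, cu("skos:exactMatch"), targets, "iri"),
                 triples(targets, RDF_TYPE,
                         vapply(xrefs$target_db, type_of, character(1)), "iri"))
  }
  stressor_parents <- names(model$stressors)[vapply(
    model$stressors, function(st) chem$cas %in% st$chemical_cas, logical(1))]
  stressor_parents <- stressor_parents[order(as.integer(stressor_parents))]
  rbind(out, link_to(s, "dcterms:isPartOf", iri_stressor(stressor_parents)))
}

#' Emit the annotation-term subjects of the model
#'
#' Cell terms, organ terms, taxonomy entries and KE components that carry an
#' ontology identifier become subjects with the fixed type of their kind,
#' their identifier, label and source. Biological objects annotated with
#' PRotein Ontology terms additionally get `skos:exactMatch` links to the
#' mapped UniProt / HGNC / NCBI Gene identifiers, each typed with its
#' database's EDAM class.
#'
#' @param model The model.
#' @param pr_table Optional PR mapping table ([read_pr_mapping()]).
#' @return Data frame of triples.
#' @export
emit_terms <- function(model, pr_table = NULL) {
  ttypes <- term_type_map()
  gtypes <- gene_db_types()
  out <- list()
  for (key in names(model$terms)) {
    term <- model$terms[[key]]
    if (is.na(term$curie)) next  # free-text terms are emitted as literals
    s <- cu(term$curie)
    type <- ttypes$type_curie[ttypes$kind == term$kind]
    block <- rbind(
      triples(s, RDF_TYPE, cu(type), "iri"),
      triples(s, cu("dc:identifier"), s, "iri"),
      opt_lit(s, "dc:title", term$label),
      opt_lit(s, "dc:source", "AOPWiki"))
    if (!is.null(pr_table) && term$kind == "object" &&
        startsWith(term$curie, "pr:")) {
      xr <- map_pr_term(term$curie, pr_table)
      if (nrow(xr)) {
        targets <- cu(xr$target_id)
        types <- gtypes$type_curie[match(xr$target_db, gtypes$token)]
        block <- rbind(block,
                       triples(s, cu("skos:exactMatch"), targets, "iri"),
                       triples(targets, RDF_TYPE, cu(types), "iri"))
      }
    }
    out[[length(out) + 1L]] <- block
  }
  if (!length(out)) return(empty_triples())
  do.call(rbind, out)
}

#' Emit the text-mapped gene graph
#'
#' KE and KER subjects link to `hgnc:` IRIs via the gene-identifier
#' predicate; each HGNC subject is typed as an HGNC gene symbol, labelled,
#' and `skos:exactMatch`-linked to its NCBI Gene / UniProt / Ensembl
#' cross-references, each typed with its database's EDAM class.
#'
#' @param matches Data frame from [scan_model_genes()].
#' @param gene_xrefs Cross-references keyed by symbol: data frame with
#'   columns `source_id` (HGNC symbol), `target_db`, `target_id`.
#' @param registry Prefix registry for the graph.
#' @return An `rdf_graph`.
#' @export
emit_gene_graph <- function(matches, gene_xrefs = NULL,
                            registry = vocab_registry()) {
  if (nrow(matches) == 0L) return(rdf_graph(registry = registry))
  gtypes <- gene_db_types()
  links <- unique(matches[c("entity_kind", "entity_id", "symbol")])
  subj <- ifelse(links$entity_kind == "ke", iri_ke(links$entity_id),
                 iri_ker(links$entity_id))
  out <- list(triples(subj, cu("edam:data_1025"), iri_hgnc(links$symbol), "iri"))
  for (sym in sort(unique(links$symbol), method = "radix")) {
    node <- iri_hgnc(sym)
    out[[length(out) + 1L]] <- rbind(
      triples(node, RDF_TYPE,
              cu(gtypes$type_curie[gtypes$token == "hgnc"]), "iri"),
      triples(node, cu("rdfs:label"), sym, "literal"))
    if (!is.null(gene_xrefs) && nrow(gene_xrefs)) {
      xr <- gene_xrefs[gene_xrefs$source_id == sym, , drop = FALSE]
      if (nrow(xr)) {
        targets <- cu(paste0(xr$target_db, ":", xr$target_id))
        types <- gtypes$type_curie[match(xr$target_db, gtypes$token)]
        out[[length(out) + 1L]] <- rbind(
          triples(node, cu("skos:exactMatch"), targets, "iri"),
          triples(targets, RDF_TYPE, cu(types), "iri"))
      }
    }
  }
  rdf_graph(out, registry = registry)
}

#' Emit VoID metadata describing the two data graphs
#'
#' Dataset descriptions (title, license, creation date, source snapshot,
#' triple and link-out counts, download names) for the main and gene graphs,
#' using the VoID, DCAT, PAV, Dublin Core and FOAF vocabularies.
#'
#' @param main_graph,genes_graph The emitted `rdf_graph`s.
#' @param config Named list: `base_iri` (VoID subject namespace), `license`,
#'   `created` (defaults to the model snapshot date passed in
#'   `snapshot_date`), `snapshot_date`, `homepage`, `main_file`,
#'   `genes_file`.
#' @return An `rdf_graph`.
#' @export
emit_void <- function(main_graph, genes_graph, config = list()) {
  cfg <- utils::modifyList(list(
    base_iri = "https://example.org/aopwikirdf/void#",
    license = "https://creativecommons.org/licenses/by/4.0/",
    snapshot_date = NA_character_,
    created = NULL,
    homepage = "https://aopwiki.org/",
    main_file = "AOP-Wiki.ttl",
    genes_file = "AOP-Wiki-genes.ttl"), config)
  if (is.null(cfg$created)) {
    cfg$created <- if (!is.na(cfg$snapshot_date)) cfg$snapshot_date
      else format(Sys.Date())
  }
  registry <- main_graph$registry
  describe <- function(name, title, graph, file) {
    s <- paste0(cfg$base_iri, name)
    dist <- paste0(cfg$base_iri, name, "-dist")
    df <- graph$triples
    linkouts <- sum(df$predicate == cu("skos:exactMatch"))
    rbind(
      triples(s, RDF_TYPE, cu("void:Dataset"), "iri"),
      triples(s, cu("dcterms:title"), title, "literal"),
      triples(s, cu("dcterms:license"), cfg$license, "iri"),
      triples(s, cu("dcterms:created"), cfg$created, "literal"),
      if (!is.na(cfg$snapshot_date)) {
        triples(s, cu("dcterms:source"),
                paste0("AOP-Wiki XML snapshot ", cfg$snapshot_date), "literal")
      } else empty_triples(),
      triples(s, cu("pav:createdWith"), "aopwikirdf R package", "literal"),
      triples(s, cu("foaf:homepage"), cfg$homepage, "iri"),
      triples(s, cu("void:triples"), as.character(nrow(df)), "typed",
              cu("xsd:integer")),
      triples(s, cu("void:distinctSubjects"),
              as.character(length(unique(df$subject))), "typed",
              cu("xsd:integer")),
      triples(s, cu("void:distinctObjects"),
              as.character(length(unique(df$object))), "typed",
              cu("xsd:integer")),
      triples(s, cu("void:dataDump"), paste0(cfg$base_iri, file), "iri"),
      triples(s, cu("dcat:distribution"), dist, "iri"),
      triples(dist, RDF_TYPE, cu("dcat:Distribution"), "iri"),
      triples(dist, cu("dcat:downloadURL"), paste0(cfg$base_iri, file), "iri"),
      # link-outs (skos:exactMatch statements) reported as a VoID linkset
      triples(paste0(cfg$base_iri, name, "-linkouts"), RDF_TYPE,
              cu("void:Linkset"), "iri"),
      triples(paste0(cfg$base_iri, name, "-linkouts"),
              cu("void:subjectsTarget"), s, "iri"),
      triples(paste0(cfg$base_iri, name, "-linkouts"), cu("void:triples"),
              as.character(linkouts), "typed", cu("xsd:integer")))
  }
  rdf_graph(list(
    describe("AOPWikiRDF", "AOP-Wiki RDF (main graph)", main_graph,
             cfg$main_file),
    describe("AOPWikiRDF-genes", "AOP-Wiki RDF (text-mapped gene graph)",
             genes_graph, cfg$genes_file)), registry = registry)
}

#' Convert a knowledge model to the three RDF graphs
#'
#' Runs the full conversion: emits all entities into the main graph, scans
#' KE/KER text for gene mentions and builds the gene graph, expands chemical
#' and gene identifiers through the mapping backend, and derives VoID
#' metadata.
#'
#' @param model An `aopwiki_model`.
#' @param dict Optional `symbol_dictionary` for gene text mapping (`NULL`
#'   disables it; the gene graph is then empty).
#' @param pr_table Optional PR mapping table.
#' @param backend Optional `mapper_backend` for chemical/gene
#'   cross-references.
#' @param void_config Configuration list passed to [emit_void()].
#' @return List with elements `main`, `genes`, `void` (each an `rdf_graph`)
#'   and `matches` (the gene text-match audit table).
#' @export
convert_model <- function(model, dict = NULL, pr_table = NULL, backend = NULL,
                          void_config = list()) {
  registry <- vocab_registry()
  blocks <- list()
  for (id in names(model$aops)) {
    blocks[[length(blocks) + 1L]] <- emit_aop(model$aops[[id]], model)
  }
  for (id in names(model$kes)) {
    blocks[[length(blocks) + 1L]] <- emit_ke(model$kes[[id]], model)
  }
  for (id in names(model$kers)) {
    blocks[[length(blocks) + 1L]] <- emit_ker(model$kers[[id]], model)
  }
  for (id in names(model$stressors)) {
    blocks[[length(blocks) + 1L]] <- emit_stressor(model$stressors[[id]], model)
  }
  for (cas in names(model$chemicals)) {
    xr <- if (!is.null(backend)) map_chemical(cas, backend) else NULL
    blocks[[length(blocks) + 1L]] <-
      emit_chemical(model$chemicals[[cas]], model, xr)
  }
  blocks[[length(blocks) + 1L]] <- emit_terms(model, pr_table)
  main <- rdf_graph(blocks, registry = registry)

  if (!is.null(dict)) {
    matches <- scan_model_genes(model, dict)
    gene_xrefs <- NULL
    if (!is.null(backend) && nrow(matches)) {
      gene_xrefs <- do.call(rbind, lapply(sort(unique(matches$symbol)),
                                          map_gene, backend = backend))
    }
    genes <- emit_gene_graph(matches, gene_xrefs, registry)
  } else {
    matches <- data.frame(entity_kind = character(0), entity_id = character(0),
                          hgnc_id = character(0), symbol = character(0),
                          surface_form = character(0),
                          field_name = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
    genes <- rdf_graph(registry = registry)
  }

  void_config$snapshot_date <- void_config$snapshot_date %||%
    model$snapshot_date
  void <- emit_void(main, genes, void_config)
  list(main = main, genes = genes, void = void, matches = matches)
}

#' Write the three Turtle files of a conversion
#'
#' @param converted Result of [convert_model()].
#' @param out_dir Output directory (created if missing).
#' @param names File names for the main, gene and VoID graphs.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_rdf_files <- function(converted, out_dir,
                            names = c(main = "AOP-Wiki.ttl",
                                      genes = "AOP-Wiki-genes.ttl",
                                      void = "AOP-Wiki-void.ttl")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, names[c("main", "genes", "void")])
  names(paths) <- c("main", "genes", "void")
  serialize_turtle(converted$main, paths[["main"]])
  serialize_turtle(converted$genes, paths[["genes"]])
  serialize_turtle(converted$void, paths[["void"]])
  invisible(paths)
}
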