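#' @keywords internal
"_PACKAGE"

.vocab_cache <- new.env(parent = emptyenv())

vocab_file <- function(name) {
  path <- system.file("extdata", "vocabulary", name, package = "aopwikirdf")
  if (!nzchar(path)) stop("vocabulary data file not found: ", name)
  path
}

read_vocab_tsv <- function(name) {
  utils::read.delim(vocab_file(name), sep = "\t", quote = "",
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Prefix registry of the RDF schema
#'
#' Returns the table of namespace prefixes used anywhere in the emitted RDF:
#' the core metadata vocabularies and domain ontologies (Dublin Core, DCMI
#' Terms, RDF Schema, FOAF, the AOP Ontology, PATO, CHEMINF, NCI Thesaurus,
#' MMO, SKOS, NCBI Taxon, GO, EDAM, PAV, VoID, DCAT), the additional
#' annotation ontologies used by key-event component terms (Cell Ontology,
#' Uberon, MI, MP, MeSH, HP, PCO, NBO, VT, PRO, FMA), and the
#' identifiers.org namespaces for AOP-Wiki entities, chemicals and genes.
#'
#' @return A data frame with columns `prefix`, `base_iri`, `category`
#'   (one of `"metadata"`, `"domain"`, `"identifier"`) and `source`.
#' @export
#' @examples
#' head(vocab_registry())
vocab_registry <- function() {
  if (is.null(.vocab_cache$registry)) {
    reg <- read_vocab_tsv("prefixes.tsv")
    stopifnot(!anyDuplicated(reg$prefix), !anyDuplicated(reg$base_iri))
    .vocab_cache$registry <- reg
  }
  .vocab_cache$registry
}

#' Resolve compact identifiers (CURIEs) to absolute IRIs
#'
#' Expands `prefix:local` compact identifiers against [vocab_registry()].
#' Identifier-category prefixes resolve to identifiers.org-style URLs, e.g.
#' `aop:38` becomes `https://identifiers.org/aop/38`.
#'
#' @param x Character vector of CURIEs (`"prefix:local"`).
#' @param registry Prefix registry, defaults to [vocab_registry()].
#' @return Character vector of absolute IRIs.
#' @export
#' @examples
#' resolve_curie(c("aop:38", "aop.events:1502"))
resolve_curie <- function(x, registry = vocab_registry()) {
  if (length(x) == 0L) return(character(0))
  sep <- regexpr(":", x, fixed = TRUE)
  if (any(sep < 0L)) stop("not a CURIE (missing ':'): ", x[sep < 0L][1L])
  prefix <- substr(x, 1L, sep - 1L)
  local <- substr(x, sep + 1L, nchar(x))
  idx <- match(prefix, registry$prefix)
  if (anyNA(idx)) stop("unknown prefix: ", unique(prefix[is.na(idx)])[1L])
  paste0(registry$base_iri[idx], local)
}

#' Compact an absolute IRI back to a CURIE where a prefix matches
#'
#' Uses the longest matching base IRI in the registry; IRIs with no
#' registered base are returned unchanged.
#'
#' @inheritParams resolve_curie
#' @return Character vector of CURIEs or unmodified IRIs.
#' @export
compact_iri <- function(x, registry = vocab_registry()) {
  if (length(x) == 0L) return(character(0))
  bases <- registry$base_iri[order(nchar(registry$base_iri), decreasing = TRUE)]
  prefixes <- registry$prefix[order(nchar(registry$base_iri), decreasing = TRUE)]
  out <- x
  for (i in seq_along(bases)) {
    hit <- startsWith(out, bases[i]) & out == x  # only compact not-yet-compacted
    if (any(hit)) {
      out[hit] <- paste0(prefixes[i], ":", substr(x[hit], nchar(bases[i]) + 1L,
                                                  nchar(x[hit])))
    }
  }
  out
}

#' Namespace prefix of an IRI, if registered
#'
#' @inheritParams resolve_curie
#' @return Character vector of registry prefixes, `NA` where no base matches.
#' @export
iri_prefix <- function(x, registry = vocab_registry()) {
  cur <- compact_iri(x, registry)
  ifelse(cur == x, NA_character_, sub(":.*$", "", cur))
}

#' Predicate schema for one entity kind
#'
#' The ordered predicate/object-kind table that drives RDF emission for a
#' given entity kind. The AOP slice has 26 predicate rows; key events, key
#' event relationships, stressors, chemicals, annotation terms and
#' text-mapped genes each have their own slice. Order is the serialization
#' order.
#'
#' @param entity_kind One of `"aop"`, `"ke"`, `"ker"`, `"stressor"`,
#'   `"chemical"`, `"term"`, `"gene"`.
#' @return Data frame with columns `entity_kind`, `ord`, `predicate`
#'   (CURIE), `object_kind`, `cardinality`, `field`, `graph`.
#' @export
#' @examples
#' nrow(schema_for("aop"))  # 26
schema_for <- function(entity_kind) {
  sch <- predicate_schema()
  out <- sch[sch$entity_kind == entity_kind, , drop = FALSE]
  if (nrow(out) == 0L) stop("unknown entity kind: ", entity_kind)
  out[order(as.integer(out$ord)), , drop = FALSE]
}

#' Full predicate schema (all entity kinds)
#' @return Data frame, see [schema_for()].
#' @export
predicate_schema <- function() {
  if (is.null(.vocab_cache$schema)) {
    .vocab_cache$schema <- read_vocab_tsv("schema.tsv")
  }
  .vocab_cache$schema
}

#' Chemical database type annotations
#'
#' Map from chemical database token to the CHEMINF class used to type its
#' identifier nodes (12 databases: CAS, ChEBI, ChemSpider, ChEMBL compound,
#' CompTox, Drugbank, HMDB, InChIKey, KEGG compound, LIPID MAPS, PubChem
#' compound, Wikidata).
#' @return Data frame with columns `token`, `type_curie`, `database`.
#' @export
chemical_db_types <- function() read_vocab_tsv("chem_db_types.tsv")

#' Gene/protein database type annotations
#'
#' Map from gene database token to the EDAM data class used to type its
#' identifier nodes (HGNC, Ensembl, Entrez Gene, UniProt).
#' @return Data frame with columns `token`, `type_curie`, `database`.
#' @export
gene_db_types <- function() read_vocab_tsv("gene_db_types.tsv")

#' Type annotations of ontology/annotation term subjects
#'
#' Cell terms, organ terms, taxonomy entries and the key-event components
#' (biological process / object / action) each carry a fixed rdf:type.
#' @return Data frame with columns `kind`, `type_curie`.
#' @export
term_type_map <- function() read_vocab_tsv("term_types.tsv")

#' BridgeDb data-source tokens
#'
#' Declarative translation between BridgeDb system codes / display names and
#' the registry database tokens used by the cross-reference layer.
#' @return Data frame with columns `system_code`, `system_name`, `token`.
#' @export
bridgedb_systems <- function() read_vocab_tsv("bridgedb_systems.tsv")

# database tokens considered in-scope per source kind
chemical_target_dbs <- function() {
  setdiff(chemical_db_types()$token, c("cas", "inchikey", "comptox"))
}
gene_target_dbs <- function() setdiff(gene_db_types()$token, "hgnc")
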