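# Validation of emitted Turtle, graph statistics, and the SPARQL query
# catalog. Validation (syntax via the Turtle reader, datatypes via explicit
# XSD lexical checks) and statistics (direct triple iteration) are computed
# in-package; the shipped SPARQL catalog expresses the same statistics for
# use against any SPARQL endpoint the graphs are loaded into.

XSD_CHECKS <- list(
  dateTime = ISO_DATETIME_PATTERN,
  date = "^[0-9]{4}-[0-9]{2}-[0-9]{2}$",
  integer = "^[+-]?[0-9]+$",
  boolean = "^(true|false|0|1)$",
  decimal = "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$",
  double = "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$")

# AOP-Wiki entity namespaces whose IRIs must be defined in-graph
internal_prefixes <- function() {
  c("aop", "aop.events", "aop.relationships", "aop.stressor")
}

check_datatypes <- function(df) {
  typed <- df[df$kind == "typed", , drop = FALSE]
  if (!nrow(typed)) return(character(0))
  errors <- character(0)
  xsd_base <- vocab_registry()$base_iri[vocab_registry()$prefix == "xsd"]
  for (i in seq_len(nrow(typed))) {
    dt <- typed$datatype[i]
    if (!startsWith(dt, xsd_base)) next
    local <- substr(dt, nchar(xsd_base) + 1L, nchar(dt))
    pattern <- XSD_CHECKS[[local]]
    if (is.null(pattern)) next
    if (!grepl(pattern, typed$object[i])) {
      errors <- c(errors, sprintf(
        "invalid xsd:%s literal \"%s\" on <%s> <%s>",
        local, typed$object[i], typed$subject[i], typed$predicate[i]))
    }
  }
  errors
}

#' Validate Turtle files
#'
#' Checks Turtle syntax (via the package's Turtle reader; parse errors carry
#' line numbers), XSD datatype lexical forms (dateTime literals must be
#' ISO-8601, integers integral, and so on), and dangling internal links
#' (AOP-Wiki entity IRIs used as objects but never defined as subjects in
#' the combined files).
#'
#' @param paths Character vector of Turtle files (validated together, so
#'   cross-file links count as defined).
#' @return A `validation_report`: list with `syntax_ok`, `syntax_errors`,
#'   `datatype_errors`, `dangling_links`, `summary`.
#' @export
validate_files <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", missing[1L])
  syntax_errors <- character(0)
  graphs <- list()
  for (p in paths) {
    g <- tryCatch(parse_turtle(p), error = function(e) conditionMessage(e))
    if (is.character(g)) syntax_errors <- c(syntax_errors, g)
    else graphs[[length(graphs) + 1L]] <- g
  }
  syntax_ok <- length(syntax_errors) == 0L
  datatype_errors <- character(0)
  dangling <- character(0)
  if (syntax_ok) {
    df <- do.call(rbind, lapply(graphs, function(g) g$triples))
    datatype_errors <- check_datatypes(df)
    objs <- unique(df$object[df$kind == "iri"])
    obj_prefix <- iri_prefix(objs)
    internal <- objs[!is.na(obj_prefix) & obj_prefix %in% internal_prefixes()]
    dangling <- sort(setdiff(internal, unique(df$subject)), method = "radix")
  }
  structure(list(
    files = paths, syntax_ok = syntax_ok, syntax_errors = syntax_errors,
    datatype_errors = datatype_errors, dangling_links = dangling,
    summary = c(files = length(paths),
                syntax_errors = length(syntax_errors),
                datatype_errors = length(datatype_errors),
                dangling_links = length(dangling))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Turtle validation of %d file(s): %s\n", length(x$files),
              if (x$syntax_ok && length(x$datatype_errors) == 0L)
                "OK" else "ERRORS"))
  for (e in x$syntax_errors) cat("  syntax: ", e, "\n", sep = "")
  for (e in x$datatype_errors) cat("  datatype: ", e, "\n", sep = "")
  if (length(x$dangling_links)) {
    cat("  dangling internal IRIs:\n")
    cat(paste0("    ", x$dangling_links, "\n"), sep = "")
  }
  invisible(x)
}

#' Compute graph statistics
#'
#' Totals (triples, distinct subjects / predicates / objects), subjects per
#' rdf:type, predicate frequency, link-out counts per external database
#' (skos:exactMatch targets partitioned by the type annotation of the
#' target node), and ontology/vocabulary namespace usage. Statistics are
#' computed by direct triple iteration; the shipped SPARQL catalog
#' ([query_catalog()]) expresses the same counts for endpoint use.
#'
#' @param graphs An `rdf_graph` or list of them (counted over the union).
#' @return A `stats_report` list.
#' @export
compute_stats <- function(graphs) {
  if (inherits(graphs, "rdf_graph")) graphs <- list(graphs)
  df <- unique(do.call(rbind, lapply(graphs, function(g) g$triples)))
  count_table <- function(x) {
    if (!length(x)) return(integer(0))
    tab <- table(x)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(names(out), method = "radix")]
  }
  type_rows <- df[df$predicate == RDF_TYPE & df$kind == "iri", , drop = FALSE]
  subject_type_counts <- count_table(
    compact_iri(type_rows$object)[!duplicated(paste(type_rows$subject,
                                                    type_rows$object))])
  predicate_frequency <- count_table(compact_iri(df$predicate))

  # link-outs: exactMatch targets partitioned by the target's database type
  em <- df[df$predicate == resolve_curie("skos:exactMatch"), , drop = FALSE]
  db_types <- rbind(chemical_db_types()[c("token", "type_curie")],
                    gene_db_types()[c("token", "type_curie")])
  target_types <- type_rows[type_rows$subject %in% em$object, , drop = FALSE]
  tok <- db_types$token[match(compact_iri(target_types$object),
                              db_types$type_curie)]
  names(tok) <- target_types$subject
  linkout_counts <- count_table(tok[match(em$object, names(tok))])

  # ontology usage: non-identifier registry namespaces per triple position
  reg <- vocab_registry()
  onto_prefixes <- reg$prefix[reg$category != "identifier"]
  all_iris <- c(df$subject, df$predicate, df$object[df$kind == "iri"])
  pfx <- iri_prefix(all_iris)
  ontology_usage <- count_table(pfx[!is.na(pfx) & pfx %in% onto_prefixes])

  structure(list(
    totals = c(triples = nrow(df),
               subjects = length(unique(df$subject)),
               predicates = length(unique(df$predicate)),
               objects = length(unique(df$object))),
    subject_type_counts = subject_type_counts,
    predicate_frequency = predicate_frequency,
    linkout_counts = linkout_counts,
    ontology_usage = ontology_usage), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Graph statistics\n")
  cat(sprintf("  triples: %d  subjects: %d  predicates: %d  objects: %d\n",
              x$totals[["triples"]], x$totals[["subjects"]],
              x$totals[["predicates"]], x$totals[["objects"]]))
  if (length(x$subject_type_counts)) {
    cat("  subjects per type:\n")
    cat(sprintf("    %s: %d\n", names(x$subject_type_counts),
                x$subject_type_counts), sep = "")
  }
  if (length(x$linkout_counts)) {
    cat("  link-outs per database:\n")
    cat(sprintf("    %s: %d\n", names(x$linkout_counts), x$linkout_counts),
        sep = "")
  }
  invisible(x)
}

#' Distinct ontology/vocabulary namespaces used by a set of graphs
#'
#' Counts the non-identifier registry namespaces appearing among predicate
#' IRIs and the IRIs participating in rdf:type statements (typed subjects
#' and their classes) — i.e. the vocabularies doing semantic work in the
#' graphs, as opposed to identifier namespaces that merely name entities.
#'
#' @param graphs An `rdf_graph` or list of them.
#' @return Sorted character vector of registry prefixes.
#' @export
ontology_namespaces <- function(graphs) {
  if (inherits(graphs, "rdf_graph")) graphs <- list(graphs)
  df <- do.call(rbind, lapply(graphs, function(g) g$triples))
  type_rows <- df[df$predicate == RDF_TYPE & df$kind == "iri", , drop = FALSE]
  iris <- unique(c(df$predicate, type_rows$subject, type_rows$object))
  reg <- vocab_registry()
  pfx <- iri_prefix(iris)
  sort(unique(pfx[!is.na(pfx) &
                    pfx %in% reg$prefix[reg$category != "identifier"]]),
       method = "radix")
}

#' The bundled SPARQL query catalog
#'
#' Statistics and browsing queries over the emitted graphs, plus the
#' federated WikiPathways template (category `"federated"`, which contains a
#' `SERVICE` clause and requires network access to a remote endpoint; it is
#' shipped as a template and not executed offline).
#'
#' @return Data frame with columns `name`, `category`, `network_required`,
#'   `path`, `sparql`.
#' @export
query_catalog <- function() {
  dir <- system.file("queries", package = "aopwikirdf")
  files <- sort(list.files(dir, pattern = "\\.rq$", full.names = TRUE))
  recs <- lapply(files, function(f) {
    lines <- readLines(f, warn = FALSE)
    grab <- function(key) {
      hit <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
      if (length(hit)) trimws(sub(paste0("^# ", key, ":"), "", hit[1L]))
      else NA_character_
    }
    data.frame(
      name = grab("name"), category = grab("category"),
      network_required = identical(grab("network"), "required"),
      path = f,
      sparql = paste(lines[!startsWith(lines, "#")], collapse = "\n"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
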