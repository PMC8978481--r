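# Pluggable identifier cross-reference backends: an offline static table
# (default) and a BridgeDb-compatible HTTP client. Chemicals expand from CAS
# to nine chemical databases; genes from HGNC to NCBI Gene, UniProt, Ensembl.

#' Construct a cross-reference record table
#'
#' @param source_id Source identifiers (bare, without database prefix).
#' @param target_db Target database tokens (registry prefixes).
#' @param target_id Target identifiers (bare).
#' @return Data frame with columns `source_id`, `target_db`, `target_id`.
#' @export
xref_records <- function(source_id, target_db, target_id) {
  data.frame(source_id = as.character(source_id),
             target_db = as.character(target_db),
             target_id = as.character(target_id), stringsAsFactors = FALSE)
}

#' Transport failure distinct from "no mapping found"
#' @param message Error message.
#' @param call Call to record.
#' @return Never returns; signals a condition of class
#'   `aopwikirdf_transport_error`.
#' @export
transport_error <- function(message, call = sys.call(-1)) {
  stop(structure(class = c("aopwikirdf_transport_error", "error", "condition"),
                 list(message = message, call = call)))
}

#' Static-table mapping backend
#'
#' Loads a four-column TSV (`source_db`, `source_id`, `target_db`,
#' `target_id`, with header) and answers lookups from it. This is the
#' offline default backend; rows with database tokens outside the registry
#' are kept but flagged with a load warning.
#'
#' @param table Path to the TSV, or an equivalent data frame.
#' @return A `mapper_backend` object.
#' @export
static_backend <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    raw <- readLines(table, warn = FALSE)
    lineno <- which(nzchar(raw))
    cells <- strsplit(raw[lineno], "\t", fixed = TRUE)
    nfield <- lengths(cells)
    if (any(nfield != 4L)) {
      bad <- which(nfield != 4L)[1L]
      stop(sprintf("malformed xref table row at line %d (expected 4 columns, got %d)",
                   lineno[bad], nfield[bad]))
    }
    tab <- as.data.frame(do.call(rbind, cells[-1L]), stringsAsFactors = FALSE)
    names(tab) <- cells[[1L]]
  } else {
    tab <- as.data.frame(table, stringsAsFactors = FALSE)
  }
  need <- c("source_db", "source_id", "target_db", "target_id")
  if (!all(need %in% names(tab))) {
    stop("xref table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- unique(tab[need])
  known <- vocab_registry()$prefix
  odd <- unique(tab$target_db[!tab$target_db %in% known])
  if (length(odd)) {
    warning("xref table contains unknown database token(s): ",
            paste(odd, collapse = ", "), " (rows kept)", call. = FALSE)
  }
  lookup <- function(source_id, source_db, target_dbs) {
    hits <- tab[tab$source_db == source_db & tab$source_id == source_id &
                  tab$target_db %in% target_dbs, , drop = FALSE]
    xref_records(hits$source_id, hits$target_db, hits$target_id)
  }
  structure(list(lookup = lookup, name = "static",
                 provenance = if (is.character(table)) table else "in-memory"),
            class = "mapper_backend")
}

#' BridgeDb-compatible HTTP mapping backend
#'
#' Issues `GET {base_url}/{organism}/xrefs/{systemCode}/{id}` requests and
#' parses the two-column plain-text response (identifier, data-source
#' display name). Data-source names are translated to registry tokens via
#' [bridgedb_systems()]; unknown data sources are ignored. HTTP or parse
#' failures raise a transport error distinct from an empty mapping; an HTTP
#' 404 means "no mapping" per BridgeDb convention.
#'
#' Network access only happens when `lookup` is called; tests inject `fetch`
#' to stay offline.
#'
#' @param base_url Service base URL.
#' @param organism Organism path segment (default `"Human"`).
#' @param fetch Function `(url) -> character vector of response lines`;
#'   defaults to [base::readLines()] over a URL connection. Must signal an
#'   error with class `http404` for a 404.
#' @return A `mapper_backend` object.
#' @export
http_backend <- function(base_url, organism = "Human", fetch = NULL) {
  if (is.null(fetch)) {
    fetch <- function(url) {
      con <- url(url, open = "r")
      on.exit(close(con))
      readLines(con, warn = FALSE)
    }
  }
  systems <- bridgedb_systems()
  source_code <- function(db) {
    code <- systems$system_code[systems$token == db]
    if (!length(code)) stop("no BridgeDb system code for database: ", db)
    code
  }
  lookup <- function(source_id, source_db, target_dbs) {
    url <- sprintf("%s/%s/xrefs/%s/%s", sub("/+$", "", base_url), organism,
                   source_code(source_db), utils::URLencode(source_id))
    lines <- tryCatch(fetch(url),
                      http404 = function(e) character(0),
                      error = function(e) {
                        transport_error(paste0("BridgeDb request failed: ",
                                               conditionMessage(e)))
                      })
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(xref_records(character(0), character(0), character(0)))
    cells <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(cells) < 2L)) {
      transport_error("malformed BridgeDb response (expected two columns)")
    }
    ids <- vapply(cells, `[[`, character(1), 1L)
    dbs <- systems$token[match(vapply(cells, `[[`, character(1), 2L),
                               systems$system_name)]
    keep <- !is.na(dbs) & dbs %in% target_dbs
    xref_records(rep(source_id, sum(keep)), dbs[keep], ids[keep])
  }
  structure(list(lookup = lookup, name = "bridgedb-http",
                 provenance = base_url), class = "mapper_backend")
}

#' @export
print.mapper_backend <- function(x, ...) {
  cat(sprintf("<mapper_backend: %s (%s)>\n", x$name, x$provenance))
  invisible(x)
}

filter_targets <- function(xr, allowed, source_label) {
  out_of_scope <- !xr$target_db %in% allowed
  if (any(out_of_scope)) {
    message(sprintf("%s: %d out-of-scope mapping(s) to %s filtered",
                    source_label, sum(out_of_scope),
                    paste(unique(xr$target_db[out_of_scope]), collapse = ", ")))
  }
  unique(xr[!out_of_scope, , drop = FALSE])
}

#' Expand a chemical CAS number to external database identifiers
#'
#' Results are restricted to the nine BridgeDb-covered chemical databases
#' (ChEBI, ChemSpider, Wikidata, ChEMBL compound, PubChem compound,
#' DrugBank, KEGG compound, LIPID MAPS, HMDB) and deduplicated.
#'
#' @param cas CAS registry number (for example `"103-90-2"`).
#' @param backend A `mapper_backend`.
#' @return Data frame of cross-references.
#' @export
map_chemical <- function(cas, backend) {
  if (!grepl(CAS_PATTERN, cas)) stop("not a valid CAS number: ", cas)
  allowed <- chemical_target_dbs()
  xr <- backend$lookup(cas, "cas", allowed)
  filter_targets(xr, allowed, paste0("cas:", cas))
}

#' Expand an HGNC gene to external database identifiers
#'
#' Results are restricted to NCBI Gene, UniProt and Ensembl, and
#' deduplicated.
#'
#' @param hgnc HGNC symbol used as identifier (for example `"UROD"`).
#' @param backend A `mapper_backend`.
#' @return Data frame of cross-references.
#' @export
map_gene <- function(hgnc, backend) {
  stopifnot(is.character(hgnc), length(hgnc) == 1L, nzchar(hgnc))
  allowed <- gene_target_dbs()
  xr <- backend$lookup(hgnc, "hgnc", allowed)
  filter_targets(xr, allowed, paste0("hgnc:", hgnc))
}
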