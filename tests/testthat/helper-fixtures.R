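# Shared fixtures and independent oracles for the test suite.

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

# canonical fixture converted once per test run
canonical_conversion <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- canonical_fixture()
      model <- suppressWarnings(parse_aopwiki_xml(fx[["xml"]]))
      dict <- build_symbol_dictionary(fx[["hgnc"]])
      pr <- read_pr_mapping(fx[["pr"]])
      backend <- static_backend(fx[["xrefs"]])
      conv <- convert_model(model, dict, pr, backend)
      cache <<- list(fx = fx, model = model, dict = dict, pr = pr,
                     backend = backend, conv = conv)
    }
    cache
  }
})

write_xml_fixture <- function(lines) {
  path <- tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>", "<data snapshot-date=\"2021-01-01\">",
               lines, "</data>"), path)
  path
}

has_triple <- function(graph, subject, predicate, object, kind = "iri") {
  df <- graph$triples
  p <- if (identical(predicate, "a")) RDF_TYPE_IRI else resolve_curie(predicate)
  any(df$subject == subject & df$predicate == p & df$object == object &
        df$kind == kind)
}

# Independent boundary-matching oracle: regex with an explicit boundary
# class and negative lookarounds, scanned with overlap continuation. Shares
# no code with scan_text (which compares flanking characters directly).
oracle_scan <- function(text, dict) {
  bclass <- "[^ \\t\\n\\r()\\[\\]{}.,;:/\"'-]"
  out <- list()
  for (i in seq_len(nrow(dict))) {
    form <- dict$form[i]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", form)
    pattern <- paste0("(?<!", bclass, ")", esc, "(?!", bclass, ")")
    from <- 1L
    while (from <= nchar(text)) {
      m <- regexpr(pattern, substr(text, from, nchar(text)), perl = TRUE,
                   ignore.case = !dict$case_sensitive[i])
      if (m < 0L) break
      pos <- from + as.integer(m) - 1L
      out[[length(out) + 1L]] <- data.frame(
        hgnc_id = dict$hgnc_id[i], start = pos - 1L,
        end = pos - 1L + nchar(form), stringsAsFactors = FALSE)
      from <- pos + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(hgnc_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end, res$hgnc_id, method = "radix"), ]
}

match_key <- function(df) {
  sort(paste(df$hgnc_id, df$start, df$end, sep = "/"))
}

# random scan-test text built from dictionary forms, embedded decoys and
# filler, joined by a mix of boundary and non-boundary characters
random_scan_text <- function(dict, target_nchar = 2000L) {
  seps <- c(" ", " ", " ", "\n", ", ", "; ", "(", ")", "/", "-", "", "_", "9")
  pieces <- character(0)
  size <- 0L
  while (size < target_nchar) {
    kind <- sample(c("form", "decoy", "filler"), 1L,
                   prob = c(0.3, 0.2, 0.5))
    piece <- switch(kind,
      form = sample(dict$form, 1L),
      decoy = paste0(sample(c("x", "pre", ""), 1L),
                     sample(dict$form, 1L),
                     sample(c("z", "ase", "7"), 1L)),
      filler = paste(sample(letters, sample(2:8, 1L), replace = TRUE),
                     collapse = ""))
    sep <- sample(seps, 1L)
    pieces <- c(pieces, piece, sep)
    size <- size + nchar(piece) + nchar(sep)
  }
  paste(pieces, collapse = "")
}

# Run a SPARQL query over Turtle files with python rdflib (independent
# engine); returns a data frame of bindings (all columns character).
rdflib_query <- function(ttl_paths, sparql) {
  qfile <- tempfile(fileext = ".rq"); writeLines(sparql, qfile)
  out <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import rdflib",
    "g = rdflib.Graph()",
    "for p in sys.argv[1:-2]:",
    "    g.parse(p, format='turtle')",
    "q = open(sys.argv[-2]).read()",
    "rows = []",
    "res = g.query(q)",
    "for row in res:",
    "    rows.append({str(v): ('' if row[i] is None else str(row[i]))",
    "                 for i, v in enumerate(res.vars)})",
    "json.dump(rows, open(sys.argv[-1], 'w'))"), script)
  status <- system2("python", c(script, ttl_paths, qfile, out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("python rdflib query failed")
  rows <- jsonlite::fromJSON(readLines(out, warn = FALSE),
                             simplifyDataFrame = TRUE)
  if (length(rows) == 0L) data.frame() else rows
}

rdflib_triple_count <- function(ttl_path) {
  as.integer(rdflib_query(ttl_path,
                          "SELECT (COUNT(*) AS ?n) WHERE { ?s ?p ?o }")$n)
}
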