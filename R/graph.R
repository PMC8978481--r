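# Triple container and Turtle I/O.
#
# Triples are held in a plain data frame with set semantics:
#   subject   absolute IRI
#   predicate absolute IRI
#   object    IRI or literal lexical form
#   kind      "iri" | "literal" | "typed"
#   datatype  datatype IRI for kind == "typed", NA otherwise

#' Build a block of triples
#'
#' Vectorized constructor for the triple table used throughout the package.
#'
#' @param subject,predicate Absolute IRIs (recycled to a common length).
#' @param object Object IRIs or literal values.
#' @param kind `"iri"`, `"literal"` or `"typed"` per triple.
#' @param datatype Datatype IRI for typed literals, `NA` otherwise.
#' @return Data frame of triples.
#' @export
triples <- function(subject, predicate, object, kind = "iri",
                    datatype = NA_character_) {
  n <- max(length(subject), length(predicate), length(object))
  if (n == 0L) return(empty_triples())
  data.frame(subject = rep_len(as.character(subject), n),
             predicate = rep_len(as.character(predicate), n),
             object = rep_len(as.character(object), n),
             kind = rep_len(as.character(kind), n),
             datatype = rep_len(as.character(datatype), n),
             stringsAsFactors = FALSE)
}

empty_triples <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), kind = character(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

#' Create an RDF graph
#'
#' A graph is a set of triples (duplicates collapse) plus the namespace
#' bindings it was built against.
#'
#' @param triples Data frame as produced by [triples()], or a list of such
#'   data frames.
#' @param registry Prefix registry used for serialization bindings.
#' @return An object of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = NULL, registry = vocab_registry()) {
  if (is.null(triples)) triples <- empty_triples()
  if (is.data.frame(triples)) triples <- list(triples)
  df <- do.call(rbind, c(triples, list(empty_triples())))
  df$datatype[df$kind != "typed"] <- NA_character_
  key <- paste(df$subject, df$predicate, df$object, df$kind,
               ifelse(is.na(df$datatype), "", df$datatype), sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(triples = df, registry = registry), class = "rdf_graph")
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @return Integer count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

#' Merge graphs
#' @param ... `rdf_graph` objects.
#' @return Combined `rdf_graph` (set union).
#' @export
graph_union <- function(...) {
  gs <- list(...)
  rdf_graph(lapply(gs, function(g) g$triples), registry = gs[[1L]]$registry)
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d subjects>\n", nrow(x$triples),
              length(unique(x$triples$subject))))
  invisible(x)
}

#' @export
as.data.frame.rdf_graph <- function(x, ...) x$triples

# ---- Turtle writing ---------------------------------------------------------

escape_turtle_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_turtle_literal <- function(x) {
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    out <- character(0)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        rep <- switch(nxt, n = "\n", r = "\r", t = "\t",
                      "\"" = "\"", "\\" = "\\", "'" = "'",
                      u = NA_character_, U = NA_character_, NULL)
        if (is.null(rep)) stop("invalid escape \\", nxt)
        if (is.na(rep)) {  # \uXXXX / \UXXXXXXXX
          nhex <- if (nxt == "u") 4L else 8L
          code <- paste(chars[(i + 2L):(i + 1L + nhex)], collapse = "")
          rep <- intToUtf8(strtoi(code, 16L))
          i <- i + nhex
        }
        out <- c(out, rep)
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# pname local parts we are willing to emit; anything else falls back to <IRI>
turtle_safe_local <- function(local) {
  grepl("^[A-Za-z0-9]([A-Za-z0-9._-]*[A-Za-z0-9_-])?$", local) &
    !grepl("\\.\\.", local)
}

format_term_turtle <- function(iri, registry) {
  cur <- compact_iri(iri, registry)
  hit <- cur != iri
  local <- sub("^[^:]*:", "", cur)
  ok <- hit & turtle_safe_local(local)
  ifelse(ok, cur, paste0("<", iri, ">"))
}

# deterministic predicate ordering: rdf:type first, then schema order, then name
predicate_rank <- function(predicates, registry = vocab_registry()) {
  sch <- predicate_schema()
  sch_iri <- resolve_curie(sch$predicate, registry)
  rank_map <- tapply(as.integer(sch$ord), sch_iri, min)
  r <- rank_map[predicates]
  r[is.na(r)] <- 500L
  r[predicates == RDF_TYPE] <- 0L
  as.integer(r)
}

#' Serialize a graph to Turtle
#'
#' Output is deterministic: prefixes in registry order (only those used),
#' subjects sorted, predicates in schema order (rdf:type first), objects
#' sorted. Plain literals are emitted unadorned; dateTime values carry an
#' explicit `xsd:dateTime` datatype.
#'
#' @param graph An `rdf_graph`.
#' @param path Output file path; directories are not created.
#' @return `path`, invisibly.
#' @export
serialize_turtle <- function(graph, path) {
  registry <- graph$registry
  df <- graph$triples
  con <- file(path, open = "wb")  # binary: identical bytes on every platform
  on.exit(close(con))
  emit <- function(lines) writeLines(lines, con, sep = "\n", useBytes = TRUE)

  all_iris <- c(df$subject, df$predicate, df$object[df$kind == "iri"],
                df$datatype[df$kind == "typed"])
  used <- unique(iri_prefix(all_iris, registry))
  used <- registry[registry$prefix %in% used, , drop = FALSE]
  if (nrow(used)) {
    emit(sprintf("@prefix %s: <%s> .", used$prefix, used$base_iri))
    emit("")
  }
  if (nrow(df) == 0L) return(invisible(path))

  fmt_object <- function(rows, i) {
    if (rows$kind[i] == "iri") {
      return(format_term_turtle(rows$object[i], registry))
    }
    lit <- paste0("\"", escape_turtle_literal(rows$object[i]), "\"")
    if (rows$kind[i] == "typed") {
      lit <- paste0(lit, "^^", format_term_turtle(rows$datatype[i], registry))
    }
    lit
  }

  df$rank <- predicate_rank(df$predicate, registry)
  subjects <- sort(unique(df$subject), method = "radix")
  for (s in subjects) {
    rows <- df[df$subject == s, , drop = FALSE]
    rows <- rows[order(rows$rank, rows$predicate, rows$object,
                       method = "radix"), , drop = FALSE]
    preds <- unique(rows$predicate)
    lines <- character(0)
    for (k in seq_along(preds)) {
      p <- preds[k]
      sel <- which(rows$predicate == p)
      pname <- if (p == RDF_TYPE) "a" else format_term_turtle(p, registry)
      objs <- vapply(sel, function(i) fmt_object(rows, i), character(1))
      lines <- c(lines, paste0("    ", pname, " ",
                               paste(objs, collapse = ", "),
                               if (k == length(preds)) " ." else " ;"))
    }
    emit(c(format_term_turtle(s, registry), lines, ""))
  }
  invisible(path)
}

# ---- Turtle reading ---------------------------------------------------------

#' Read a Turtle file into an RDF graph
#'
#' A self-contained reader for the Turtle subset the package emits (and the
#' common core of the language: prefix declarations, IRIs, prefixed names,
#' `a`, object/predicate lists, short and long quoted literals, escapes,
#' datatyped literals, comments). Blank nodes and language tags are not
#' supported and raise an error.
#'
#' @param path Turtle file.
#' @param registry Prefix registry attached to the returned graph.
#' @return An `rdf_graph`.
#' @export
parse_turtle <- function(path, registry = vocab_registry()) {
  text <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  toks <- turtle_tokens(text, path)
  turtle_build_graph(toks, path, registry)
}

turtle_tokens <- function(text, path = "<text>") {
  n <- nchar(text)
  newlines <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  if (identical(as.integer(newlines), -1L)) newlines <- integer(0)
  line_of <- function(pos) 1L + sum(newlines < pos)
  fail <- function(pos, msg) {
    stop(sprintf("%s:%d: Turtle syntax error: %s", path, line_of(pos), msg),
         call. = FALSE)
  }
  types <- character(0); values <- character(0); lines <- integer(0)
  push <- function(type, value, pos) {
    types[[length(types) + 1L]] <<- type
    values[[length(values) + 1L]] <<- value
    lines[[length(lines) + 1L]] <<- line_of(pos)
  }
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      i <- if (nl < 0L) n + 1L else i + nl
      next
    }
    if (ch == "<") {
      end <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (end < 0L) fail(i, "unterminated IRI")
      push("iri", substr(text, i + 1L, i + end - 2L), i)
      i <- i + end
      next
    }
    if (ch == "\"") {
      if (substr(text, i, i + 2L) == "\"\"\"") {
        rest <- substr(text, i + 3L, n)
        end <- regexpr("\"\"\"", rest, fixed = TRUE)
        if (end < 0L) fail(i, "unterminated long literal")
        push("literal", unescape_turtle_literal(substr(rest, 1L, end - 1L)), i)
        i <- i + 3L + end + 2L
        next
      }
      j <- i + 1L
      repeat {
        if (j > n) fail(i, "unterminated literal")
        cj <- substr(text, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\n") fail(i, "newline in short literal")
        if (cj == "\"") break
        j <- j + 1L
      }
      push("literal", unescape_turtle_literal(substr(text, i + 1L, j - 1L)), i)
      i <- j + 1L
      next
    }
    if (substr(text, i, i + 1L) == "^^") { push("datatype-marker", "^^", i); i <- i + 2L; next }
    if (ch %in% c(".", ",", ";")) { push("punct", ch, i); i <- i + 1L; next }
    if (ch == "@") {
      m <- regmatches(substr(text, i, n), regexpr("^@[A-Za-z]+", substr(text, i, n)))
      if (identical(m, "@prefix")) { push("at-prefix", m, i); i <- i + nchar(m); next }
      fail(i, paste0("unsupported directive or language tag: ", m))
    }
    if (ch == "_") fail(i, "blank nodes are not supported")
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z][A-Za-z0-9._-]*:[A-Za-z0-9._%:-]*|^[A-Za-z][A-Za-z0-9._-]*:?",
                            substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      # trailing '.' belongs to the statement terminator, not the name
      while (endsWith(m, ".")) m <- substr(m, 1L, nchar(m) - 1L)
      if (identical(m, "a")) push("a", "a", i)
      else if (grepl(":", m, fixed = TRUE)) push("pname", m, i)
      else fail(i, paste0("unexpected token: ", m))
      i <- i + nchar(m)
      next
    }
    fail(i, paste0("unexpected character: ", ch))
  }
  list(types = types, values = values, lines = lines, path = path)
}

turtle_build_graph <- function(toks, path, registry) {
  types <- toks$types; values <- toks$values; lines <- toks$lines
  fail <- function(k, msg) {
    ln <- if (k <= length(lines)) lines[k] else lines[length(lines)]
    stop(sprintf("%s:%d: Turtle syntax error: %s", path, ln, msg), call. = FALSE)
  }
  prefixes <- character(0)
  expand <- function(k) {
    if (types[k] == "iri") return(values[k])
    if (types[k] == "a") return(RDF_TYPE)
    if (types[k] != "pname") fail(k, "expected IRI or prefixed name")
    sep <- regexpr(":", values[k], fixed = TRUE)
    p <- substr(values[k], 1L, sep - 1L)
    if (!p %in% names(prefixes)) fail(k, paste0("undeclared prefix: ", p))
    paste0(prefixes[[p]], substr(values[k], sep + 1L, nchar(values[k])))
  }
  acc <- list(); k <- 1L; N <- length(types)
  while (k <= N) {
    if (types[k] == "at-prefix") {
      if (k + 2L > N || types[k + 1L] != "pname" || types[k + 2L] != "iri")
        fail(k, "malformed @prefix")
      pname <- sub(":$", "", values[k + 1L])
      prefixes[[pname]] <- values[k + 2L]
      if (k + 3L > N || values[k + 3L] != ".") fail(k, "@prefix missing '.'")
      k <- k + 4L
      next
    }
    subj <- expand(k); k <- k + 1L
    repeat {  # predicate-object lists
      if (k > N) fail(k, "statement not terminated")
      pred <- expand(k); k <- k + 1L
      repeat {  # object list
        if (k > N) fail(k, "missing object")
        if (types[k] %in% c("iri", "pname", "a")) {
          acc[[length(acc) + 1L]] <- triples(subj, pred, expand(k), "iri")
          k <- k + 1L
        } else if (types[k] == "literal") {
          val <- values[k]; k <- k + 1L
          if (k <= N && types[k] == "datatype-marker") {
            k <- k + 1L
            if (k > N) fail(k, "missing datatype")
            acc[[length(acc) + 1L]] <- triples(subj, pred, val, "typed", expand(k))
            k <- k + 1L
          } else {
            acc[[length(acc) + 1L]] <- triples(subj, pred, val, "literal")
          }
        } else fail(k, "expected object term")
        if (k <= N && types[k] == "punct" && values[k] == ",") { k <- k + 1L; next }
        break
      }
      if (k > N || types[k] != "punct") fail(k, "expected ';' ',' or '.'")
      if (values[k] == ";") {
        k <- k + 1L
        # tolerate trailing ';' before '.'
        if (k <= N && types[k] == "punct" && values[k] == ".") { k <- k + 1L; break }
        next
      }
      if (values[k] == ".") { k <- k + 1L; break }
      fail(k, "expected ';' or '.'")
    }
  }
  rdf_graph(acc, registry = registry)
}
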