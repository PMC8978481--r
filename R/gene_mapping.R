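# HGNC gene-symbol dictionary, boundary-aware text matching, and PRotein
# Ontology to gene/protein identifier mapping.

# characters accepted as token boundaries around a dictionary form
BOUNDARY_CHARS <- c(" ", "\t", "\n", "\r", "(", ")", "[", "]", "{", "}",
                    ".", ",", ";", ":", "/", "\"", "'", "-")

#' Read an HGNC gene table
#'
#' Tab-separated with header columns `hgnc_id`, `symbol`, `name`,
#' `alias_symbol`, `alias_name`; multi-valued alias columns are
#' pipe-separated.
#'
#' @param path TSV file.
#' @return Data frame of HGNC records.
#' @export
read_hgnc_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("hgnc_id", "symbol", "name", "alias_symbol", "alias_name")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("HGNC table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(tab$symbol))) stop("HGNC table has empty approved symbols")
  if (anyDuplicated(tab$symbol)) {
    stop("HGNC table has duplicated approved symbols")
  }
  tab
}

hgnc_numeric_id <- function(hgnc_id) {
  suppressWarnings(as.integer(sub("^HGNC:", "", hgnc_id)))
}

#' Build the surface-form dictionary for gene text matching
#'
#' Collects approved symbols, full gene names, alias symbols and alias names
#' into one lookup table. Symbols and alias symbols match case-sensitively;
#' full names and alias names match case-insensitively. A form matches in
#' text only when flanked by separator characters or string boundaries, so
#' symbols embedded in longer tokens never match. Surface-form collisions
#' are resolved deterministically (approved symbol > name > alias symbol >
#' alias name; ties to the lowest numeric HGNC id) and logged in the
#' `collisions` attribute.
#'
#' @param hgnc_table Data frame from [read_hgnc_table()] or a path to the
#'   TSV.
#' @param min_length Minimum surface-form length (shorter forms dropped).
#' @param stop_list Character vector of surface forms to exclude (known
#'   ambiguous symbols).
#' @return A `symbol_dictionary` object: data frame of (form, hgnc_id,
#'   symbol, kind, case_sensitive) with attributes `collisions` and
#'   `boundary_chars`.
#' @export
build_symbol_dictionary <- function(hgnc_table, min_length = 2L,
                                    stop_list = character(0)) {
  if (is.character(hgnc_table) && length(hgnc_table) == 1L) {
    hgnc_table <- read_hgnc_table(hgnc_table)
  }
  need <- c("hgnc_id", "symbol", "name", "alias_symbol", "alias_name")
  miss <- setdiff(need, names(hgnc_table))
  if (length(miss)) {
    stop("HGNC table is missing column(s): ", paste(miss, collapse = ", "))
  }
  split_pipe <- function(x) {
    parts <- trimws(unlist(strsplit(x, "|", fixed = TRUE), use.names = FALSE))
    parts[nzchar(parts)]
  }
  rows <- list()
  add <- function(form, rec, kind, case_sensitive) {
    if (!length(form)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      form = form, hgnc_id = rec$hgnc_id, symbol = rec$symbol, kind = kind,
      case_sensitive = case_sensitive, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(hgnc_table))) {
    rec <- hgnc_table[i, ]
    add(rec$symbol, rec, "symbol", TRUE)
    if (nzchar(rec$name)) add(rec$name, rec, "name", FALSE)
    add(split_pipe(rec$alias_symbol), rec, "alias_symbol", TRUE)
    add(split_pipe(rec$alias_name), rec, "alias_name", FALSE)
  }
  dict <- do.call(rbind, rows)
  dict <- dict[nchar(dict$form) >= min_length, , drop = FALSE]
  dict <- dict[!dict$form %in% stop_list, , drop = FALSE]
  # collision resolution: match key is the form under its matching case rule
  dict$match_key <- ifelse(dict$case_sensitive, dict$form, tolower(dict$form))
  kind_rank <- c(symbol = 1L, name = 2L, alias_symbol = 3L, alias_name = 4L)
  dict$rank <- kind_rank[dict$kind]
  dict$numid <- hgnc_numeric_id(dict$hgnc_id)
  ord <- order(dict$match_key, dict$rank, dict$numid, method = "radix")
  dict <- dict[ord, , drop = FALSE]
  dup <- duplicated(dict$match_key)
  collisions <- unique(dict$match_key[dup])
  losers <- dict[dup, c("form", "hgnc_id", "kind")]
  dict <- dict[!dup, , drop = FALSE]
  dict$rank <- NULL; dict$numid <- NULL
  rownames(dict) <- NULL
  structure(dict,
            collisions = if (length(collisions)) {
              data.frame(form = collisions, stringsAsFactors = FALSE)
            } else NULL,
            dropped = losers,
            boundary_chars = BOUNDARY_CHARS,
            class = c("symbol_dictionary", "data.frame"))
}

is_boundary <- function(ch) ch == "" | ch %in% BOUNDARY_CHARS

# all (possibly overlapping) fixed-string match positions of needle in hay
find_all_fixed <- function(hay, needle) {
  pos <- integer(0)
  start <- 1L
  n <- nchar(hay)
  while (start <= n) {
    hit <- regexpr(needle, substr(hay, start, n), fixed = TRUE)
    if (hit < 0L) break
    p <- start + as.integer(hit) - 1L
    pos[[length(pos) + 1L]] <- p
    start <- p + 1L
  }
  pos
}

#' Scan free text for gene mentions
#'
#' Finds all exact, boundary-delimited occurrences of dictionary forms in
#' `text`. Character spans are 0-based half-open over the input text.
#'
#' @param text Character scalar (plain text; markup stripped upstream).
#' @param dict A `symbol_dictionary`.
#' @param field_name Label recorded with each match (which entity field the
#'   text came from).
#' @return Data frame of matches: `hgnc_id`, `symbol`, `surface_form`,
#'   `field_name`, `start`, `end`.
#' @export
#' @examples
#' hg <- data.frame(hgnc_id = "HGNC:12591", symbol = "UROD",
#'                  name = "uroporphyrinogen decarboxylase",
#'                  alias_symbol = "", alias_name = "")
#' dict <- build_symbol_dictionary(hg)
#' scan_text("Reduced UROD enzyme activity", dict)
scan_text <- function(text, dict, field_name = "text") {
  empty <- data.frame(hgnc_id = character(0), symbol = character(0),
                      surface_form = character(0), field_name = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text) || nrow(dict) == 0L) return(empty)
  out <- list()
  nc <- nchar(text)
  lower_text <- tolower(text)
  for (i in seq_len(nrow(dict))) {
    form <- dict$form[i]
    hay <- if (dict$case_sensitive[i]) text else lower_text
    needle <- if (dict$case_sensitive[i]) form else tolower(form)
    hits <- find_all_fixed(hay, needle)
    if (!length(hits)) next
    len <- nchar(form)
    for (pos in hits) {
      before <- if (pos > 1L) substr(text, pos - 1L, pos - 1L) else ""
      after <- if (pos + len <= nc) substr(text, pos + len, pos + len) else ""
      if (is_boundary(before) && is_boundary(after)) {
        out[[length(out) + 1L]] <- data.frame(
          hgnc_id = dict$hgnc_id[i], symbol = dict$symbol[i],
          surface_form = substr(text, pos, pos + len - 1L),
          field_name = field_name, start = pos - 1L, end = pos - 1L + len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$hgnc_id, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# The five text fields scanned for gene mentions
GENE_SCAN_FIELDS <- c("ke_description", "mie_ao_section", "ker_description",
                      "biological_plausibility", "empirical_support")

#' Scan a knowledge model's KE and KER text fields for gene mentions
#'
#' Scans KE descriptions, the MIE/AO-specific sections of KEs, KER
#' descriptions, and the biological-plausibility and empirical-support
#' sections of KERs. The full match list is returned for audit; triple
#' emission deduplicates to one gene per entity.
#'
#' @param model An `aopwiki_model`.
#' @param dict A `symbol_dictionary`.
#' @return Data frame of matches with `entity_kind` (`"ke"`/`"ker"`),
#'   `entity_id`, plus the [scan_text()] columns.
#' @export
scan_model_genes <- function(model, dict) {
  out <- list()
  note <- function(kind, id, text, field) {
    m <- scan_text(text, dict, field)
    if (nrow(m)) {
      out[[length(out) + 1L]] <<- cbind(
        data.frame(entity_kind = kind, entity_id = id,
                   stringsAsFactors = FALSE), m)
    }
  }
  for (id in names(model$kes)) {
    ke <- model$kes[[id]]
    note("ke", id, ke$description, "ke_description")
    note("ke", id, ke$mie_description, "mie_ao_section")
    note("ke", id, ke$ao_description, "mie_ao_section")
  }
  for (id in names(model$kers)) {
    ker <- model$kers[[id]]
    note("ker", id, ker$description, "ker_description")
    note("ker", id, ker$biological_plausibility, "biological_plausibility")
    note("ker", id, ker$empirical_support, "empirical_support")
  }
  if (!length(out)) {
    return(data.frame(entity_kind = character(0), entity_id = character(0),
                      hgnc_id = character(0), symbol = character(0),
                      surface_form = character(0), field_name = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a PRotein Ontology mapping table
#'
#' Three tab-separated columns without header, mirroring the promapping
#' dialect: PR CURIE, target CURIE (`uniprot:`, `hgnc:` or `ncbigene:`),
#' relation. All relations are treated as mappable.
#'
#' @param path TSV file.
#' @return Data frame with columns `pr`, `target`, `relation`.
#' @export
read_pr_mapping <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) == 2L) tab$V3 <- "exact"
  if (ncol(tab) != 3L) stop("PR mapping table must have 2 or 3 columns")
  names(tab) <- c("pr", "target", "relation")
  bad <- !grepl("^(PR|pr):[0-9]{9}$", tab$pr)
  if (any(bad)) {
    stop("malformed PR id(s) in mapping table: ",
         paste(utils::head(tab$pr[bad], 3L), collapse = ", "))
  }
  tab$pr <- normalize_term_curie(tab$pr)
  tab
}

#' Map a PRotein Ontology term to gene/protein identifiers
#'
#' @param pr A `pr:` CURIE (for example `"pr:000008478"`).
#' @param table Data frame from [read_pr_mapping()].
#' @return Data frame of cross-references (`source_id`, `target_db`,
#'   `target_id`); zero rows when the PR id is absent from the table.
#' @export
map_pr_term <- function(pr, table) {
  if (!grepl("^(PR|pr):", pr)) stop("not a PRotein Ontology CURIE: ", pr)
  pr <- normalize_term_curie(pr)
  hits <- table[table$pr == pr, , drop = FALSE]
  if (nrow(hits) == 0L) {
    message("no PR mapping for ", pr)
    return(xref_records(character(0), character(0), character(0)))
  }
  target <- vapply(hits$target, normalize_term_curie, character(1),
                   USE.NAMES = FALSE)
  db <- sub(":.*$", "", target)
  keep <- db %in% c("uniprot", "hgnc", "ncbigene")
  xref_records(rep(pr, sum(keep)), db[keep], target[keep])
}
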