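# Parse AOP-Wiki-style XML dumps into a typed in-memory knowledge model.
#
# The real quarterly dump's element dialect is not standardised, so parsing is
# driven by a dialect mapping (element / attribute names per field). The
# package documents and defaults to its own fixture dialect; a YAML dialect
# file adapts real dumps without code changes.

#' Default XML dialect mapping
#'
#' Element and attribute names of the documented fixture dialect, optionally
#' overridden from a YAML file whose structure mirrors the returned list.
#' Multi-valued text fields (creators, synonyms) are split on `delimiter`.
#'
#' @param path Optional YAML file with (partial) overrides.
#' @return Nested named list mapping model fields to element/attribute names.
#' @export
aopwiki_dialect <- function(path = NULL) {
  d <- list(
    root = "data",
    snapshot_attr = "snapshot-date",
    delimiter = "\n",
    term_attr = "term", label_attr = "label", text_attr = "text",
    aop = list(
      element = "aop", id = "id", title = "title",
      alternative_title = "alternative-title", creators = "creators",
      abstract = "abstract", description = "description", status = "status",
      created = "created", modified = "modified",
      key_events = "key-events", key_event_ref = "key-event",
      mies = "molecular-initiating-events", aos = "adverse-outcomes",
      kers = "key-event-relationships",
      ker_ref = "key-event-relationship",
      stressors = "stressors", stressor_ref = "stressor",
      sex_applicability = "sex-applicability", life_stage = "life-stage",
      applicability = "applicability",
      quantitative_considerations = "quantitative-considerations",
      weight_of_evidence = "weight-of-evidence",
      potential_applications = "potential-applications",
      overall_assessment = "overall-assessment",
      ke_essentiality = "ke-essentiality"),
    ke = list(
      element = "key-event", id = "id", title = "title",
      alternative_title = "alternative-title",
      bio_level = "biological-organization-level",
      description = "description",
      measurement_method = "measurement-method",
      mie_description = "mie-description", ao_description = "ao-description",
      cell_term = "cell-term", organ_term = "organ-term",
      process_term = "biological-process", object_term = "biological-object",
      action_term = "biological-action", taxonomy = "taxonomy",
      stressors = "stressors", stressor_ref = "stressor",
      sex_applicability = "sex-applicability", life_stage = "life-stage"),
    ker = list(
      element = "key-event-relationship", id = "id",
      upstream = "upstream", downstream = "downstream",
      description = "description",
      biological_plausibility = "biological-plausibility",
      empirical_support = "empirical-support",
      uncertainties = "uncertainties", taxonomy = "taxonomy",
      sex_applicability = "sex-applicability", life_stage = "life-stage",
      created = "created", modified = "modified"),
    stressor = list(
      element = "stressor", id = "id", title = "title",
      description = "description", chemical = "chemical", cas_attr = "cas",
      created = "created", modified = "modified"),
    chemical = list(
      element = "chemical", cas_attr = "cas", name = "name",
      synonym = "synonym", inchikey = "inchikey", comptox = "comptox"))
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    d <- utils::modifyList(d, ov)
  }
  d
}

child_text <- function(node, name) {
  if (is.na(name) || is.null(name)) return(NA_character_)
  kid <- xml2::xml_find_first(node, name)
  if (inherits(kid, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(kid)
  if (!nzchar(trimws(txt))) NA_character_ else txt
}

split_multi <- function(x, delimiter) {
  if (is.na(x)) return(character(0))
  parts <- trimws(strsplit(x, delimiter, fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

ref_ids <- function(node, wrapper, ref, attr = "id") {
  w <- xml2::xml_find_first(node, wrapper)
  if (inherits(w, "xml_missing")) return(character(0))
  kids <- xml2::xml_find_all(w, ref)
  ids <- xml2::xml_attr(kids, attr)
  ids[!is.na(ids) & nzchar(ids)]
}

normalize_term_curie <- function(x) {
  sep <- regexpr(":", x, fixed = TRUE)
  hit <- sep > 0L
  x[hit] <- paste0(tolower(substr(x[hit], 1L, sep[hit] - 1L)),
                   substr(x[hit], sep[hit], nchar(x[hit])))
  x
}

# Parse one term-reference element into a TermEntry (list) or NULL
parse_term_node <- function(node, kind, dialect, registry, warn) {
  curie <- xml2::xml_attr(node, dialect$term_attr)
  freetext <- xml2::xml_attr(node, dialect$text_attr)
  label <- xml2::xml_attr(node, dialect$label_attr)
  if (!is.na(curie) && nzchar(curie)) {
    curie <- normalize_term_curie(curie)
    prefix <- sub(":.*$", "", curie)
    if (!prefix %in% registry$prefix[registry$category != "metadata"]) {
      warn(sprintf("term '%s' (%s) has unregistered ontology prefix '%s'; kept as free text",
                   curie, kind, prefix))
      return(list(kind = kind, curie = NA_character_, free_text = curie,
                  label = if (is.na(label)) curie else label))
    }
    return(list(kind = kind, curie = curie, free_text = NA_character_,
                label = if (is.na(label)) curie else label))
  }
  if (!is.na(freetext) && nzchar(freetext)) {
    return(list(kind = kind, curie = NA_character_, free_text = freetext,
                label = if (is.na(label)) freetext else label))
  }
  txt <- trimws(xml2::xml_text(node))
  if (nzchar(txt)) {
    return(list(kind = kind, curie = NA_character_, free_text = txt,
                label = txt))
  }
  warn(sprintf("empty %s term reference skipped", kind))
  NULL
}

term_key <- function(term) {
  if (!is.na(term$curie)) term$curie else paste0("text:", term$free_text)
}

#' Parse an AOP-Wiki-style XML dump
#'
#' Reads the XML into a validated knowledge model covering the nine parsed
#' components: AOPs, key events (KEs), key event relationships (KERs),
#' stressors, chemicals, taxonomy terms, cell terms, organ terms, and KE
#' component terms (biological process / object / action). Entities missing
#' an id or title are skipped with a warning; dangling cross-references are
#' collected, never fatal.
#'
#' @param path XML file.
#' @param dialect Dialect mapping, see [aopwiki_dialect()].
#' @return An object of class `aopwiki_model` with elements `aops`, `kes`,
#'   `kers`, `stressors`, `chemicals`, `terms` (named lists keyed by id),
#'   `snapshot_date`, `source_path`, `warnings`, `dangling`, `skipped`.
#' @export
parse_aopwiki_xml <- function(path, dialect = aopwiki_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)  # malformed XML fails here with line number
  root <- xml2::xml_root(doc)
  registry <- vocab_registry()
  warnings <- character(0)
  warn <- function(msg) {
    warnings[[length(warnings) + 1L]] <<- msg
    warning(msg, call. = FALSE)
  }
  skipped <- c(aop = 0L, ke = 0L, ker = 0L, stressor = 0L, chemical = 0L)
  terms <- list()
  add_term <- function(term) {
    if (is.null(term)) return(NULL)
    key <- term_key(term)
    if (is.null(terms[[key]])) terms[[key]] <<- term
    key
  }
  d <- dialect

  check_timestamp <- function(x, what, id) {
    if (is.na(x)) return(NA_character_)
    x <- trimws(x)
    if (!grepl(ISO_DATETIME_PATTERN, x)) {
      warn(sprintf("%s %s: timestamp '%s' is not ISO-8601; dropped", what, id, x))
      return(NA_character_)
    }
    x
  }

  # --- key events ------------------------------------------------------------
  kes <- list()
  for (node in xml2::xml_find_all(root, d$ke$element)) {
    id <- xml2::xml_attr(node, d$ke$id)
    title <- child_text(node, d$ke$title)
    if (is.na(id) || !nzchar(id) || is.na(title)) {
      warn("key event without id or title skipped")
      skipped[["ke"]] <- skipped[["ke"]] + 1L
      next
    }
    if (!is.null(kes[[id]])) {
      warn(sprintf("duplicate key event id %s skipped", id))
      skipped[["ke"]] <- skipped[["ke"]] + 1L
      next
    }
    grab_terms <- function(el, kind) {
      nodes <- xml2::xml_find_all(node, el)
      keys <- vapply(nodes, function(nd) {
        k <- add_term(parse_term_node(nd, kind, d, registry, warn))
        if (is.null(k)) NA_character_ else k
      }, character(1))
      keys[!is.na(keys)]
    }
    cell <- grab_terms(d$ke$cell_term, "cell")
    organ <- grab_terms(d$ke$organ_term, "organ")
    kes[[id]] <- list(
      id = as.integer(id), title = title,
      alternative_title = child_text(node, d$ke$alternative_title),
      bio_level = child_text(node, d$ke$bio_level),
      description = child_text(node, d$ke$description),
      measurement_method = child_text(node, d$ke$measurement_method),
      mie_description = child_text(node, d$ke$mie_description),
      ao_description = child_text(node, d$ke$ao_description),
      cell_term = if (length(cell)) cell[[1L]] else NA_character_,
      organ_term = if (length(organ)) organ[[1L]] else NA_character_,
      process_terms = grab_terms(d$ke$process_term, "process"),
      object_terms = grab_terms(d$ke$object_term, "object"),
      action_terms = grab_terms(d$ke$action_term, "action"),
      taxa = grab_terms(d$ke$taxonomy, "taxonomy"),
      stressor_ids = ref_ids(node, d$ke$stressors, d$ke$stressor_ref),
      sex_applicability = child_text(node, d$ke$sex_applicability),
      life_stage = child_text(node, d$ke$life_stage))
  }

  # --- AOPs -------------------------------------------------------------------
  aops <- list()
  for (node in xml2::xml_find_all(root, d$aop$element)) {
    id <- xml2::xml_attr(node, d$aop$id)
    title <- child_text(node, d$aop$title)
    if (is.na(id) || !nzchar(id) || is.na(title)) {
      warn("AOP without id or title skipped")
      skipped[["aop"]] <- skipped[["aop"]] + 1L
      next
    }
    if (!is.null(aops[[id]])) {
      warn(sprintf("duplicate AOP id %s skipped", id))
      skipped[["aop"]] <- skipped[["aop"]] + 1L
      next
    }
    ke_ids <- ref_ids(node, d$aop$key_events, d$aop$key_event_ref)
    mie_ids <- ref_ids(node, d$aop$mies, d$aop$key_event_ref)
    ao_ids <- ref_ids(node, d$aop$aos, d$aop$key_event_ref)
    bad_mie <- setdiff(mie_ids, ke_ids)
    if (length(bad_mie)) {
      warn(sprintf("AOP %s: MIE id(s) %s not in its key event list; dropped",
                   id, paste(bad_mie, collapse = ", ")))
      mie_ids <- intersect(mie_ids, ke_ids)
    }
    bad_ao <- setdiff(ao_ids, ke_ids)
    if (length(bad_ao)) {
      warn(sprintf("AOP %s: AO id(s) %s not in its key event list; dropped",
                   id, paste(bad_ao, collapse = ", ")))
      ao_ids <- intersect(ao_ids, ke_ids)
    }
    created <- check_timestamp(child_text(node, d$aop$created), "AOP", id)
    modified <- check_timestamp(child_text(node, d$aop$modified), "AOP", id)
    if (!is.na(created) && !is.na(modified) && created > modified) {
      warn(sprintf("AOP %s: created (%s) is after modified (%s)",
                   id, created, modified))
    }
    aops[[id]] <- list(
      id = as.integer(id), title = title,
      alternative_title = child_text(node, d$aop$alternative_title),
      creators = split_multi(child_text(node, d$aop$creators), d$delimiter),
      abstract = child_text(node, d$aop$abstract),
      description = child_text(node, d$aop$description),
      status = child_text(node, d$aop$status),
      created = created, modified = modified,
      ke_ids = ke_ids, mie_ids = mie_ids, ao_ids = ao_ids,
      ker_ids = ref_ids(node, d$aop$kers, d$aop$ker_ref),
      stressor_ids = ref_ids(node, d$aop$stressors, d$aop$stressor_ref),
      sex_applicability = child_text(node, d$aop$sex_applicability),
      life_stage = child_text(node, d$aop$life_stage),
      applicability_text = child_text(node, d$aop$applicability),
      quantitative_considerations =
        child_text(node, d$aop$quantitative_considerations),
      weight_of_evidence = child_text(node, d$aop$weight_of_evidence),
      potential_applications = child_text(node, d$aop$potential_applications),
      overall_assessment = child_text(node, d$aop$overall_assessment),
      ke_essentiality = child_text(node, d$aop$ke_essentiality))
  }

  # --- KERs -------------------------------------------------------------------
  kers <- list()
  for (node in xml2::xml_find_all(root, d$ker$element)) {
    id <- xml2::xml_attr(node, d$ker$id)
    up <- xml2::xml_attr(node, d$ker$upstream)
    down <- xml2::xml_attr(node, d$ker$downstream)
    if (is.na(id) || !nzchar(id) || is.na(up) || is.na(down)) {
      warn("key event relationship without id/upstream/downstream skipped")
      skipped[["ker"]] <- skipped[["ker"]] + 1L
      next
    }
    if (identical(up, down)) {
      warn(sprintf("KER %s links key event %s to itself; skipped", id, up))
      skipped[["ker"]] <- skipped[["ker"]] + 1L
      next
    }
    if (!is.null(kers[[id]])) {
      warn(sprintf("duplicate KER id %s skipped", id))
      skipped[["ker"]] <- skipped[["ker"]] + 1L
      next
    }
    grab_taxa <- function() {
      nodes <- xml2::xml_find_all(node, d$ker$taxonomy)
      keys <- vapply(nodes, function(nd) {
        k <- add_term(parse_term_node(nd, "taxonomy", d, registry, warn))
        if (is.null(k)) NA_character_ else k
      }, character(1))
      keys[!is.na(keys)]
    }
    kers[[id]] <- list(
      id = as.integer(id), upstream_ke = up, downstream_ke = down,
      description = child_text(node, d$ker$description),
      biological_plausibility = child_text(node, d$ker$biological_plausibility),
      empirical_support = child_text(node, d$ker$empirical_support),
      uncertainties = child_text(node, d$ker$uncertainties),
      taxa = grab_taxa(),
      sex_applicability = child_text(node, d$ker$sex_applicability),
      life_stage = child_text(node, d$ker$life_stage),
      created = check_timestamp(child_text(node, d$ker$created), "KER", id),
      modified = check_timestamp(child_text(node, d$ker$modified), "KER", id))
  }

  # --- stressors --------------------------------------------------------------
  stressors <- list()
  for (node in xml2::xml_find_all(root, d$stressor$element)) {
    id <- xml2::xml_attr(node, d$stressor$id)
    title <- child_text(node, d$stressor$title)
    if (is.na(id) || !nzchar(id) || is.na(title)) {
      warn("stressor without id or title skipped")
      skipped[["stressor"]] <- skipped[["stressor"]] + 1L
      next
    }
    if (!is.null(stressors[[id]])) {
      warn(sprintf("duplicate stressor id %s skipped", id))
      skipped[["stressor"]] <- skipped[["stressor"]] + 1L
      next
    }
    cas <- xml2::xml_attr(xml2::xml_find_all(node, d$stressor$chemical),
                          d$stressor$cas_attr)
    cas <- cas[!is.na(cas)]
    bad <- cas[!grepl(CAS_PATTERN, cas)]
    if (length(bad)) {
      warn(sprintf("stressor %s: invalid CAS number(s) %s dropped",
                   id, paste(bad, collapse = ", ")))
      cas <- setdiff(cas, bad)
    }
    stressors[[id]] <- list(
      id = as.integer(id), title = title,
      description = child_text(node, d$stressor$description),
      chemical_cas = cas,
      created = check_timestamp(child_text(node, d$stressor$created),
                                "stressor", id),
      modified = check_timestamp(child_text(node, d$stressor$modified),
                                 "stressor", id))
  }

  # --- chemicals ---------------------------------------------------------------
  chemicals <- list()
  for (node in xml2::xml_find_all(root, d$chemical$element)) {
    cas <- xml2::xml_attr(node, d$chemical$cas_attr)
    name <- child_text(node, d$chemical$name)
    if (is.na(cas) || !grepl(CAS_PATTERN, cas) || is.na(name)) {
      warn("chemical without valid CAS or name skipped")
      skipped[["chemical"]] <- skipped[["chemical"]] + 1L
      next
    }
    if (!is.null(chemicals[[cas]])) {
      warn(sprintf("duplicate chemical CAS %s skipped", cas))
      skipped[["chemical"]] <- skipped[["chemical"]] + 1L
      next
    }
    inchikey <- child_text(node, d$chemical$inchikey)
    if (!is.na(inchikey) && !grepl(INCHIKEY_PATTERN, inchikey)) {
      warn(sprintf("chemical %s: malformed InChIKey '%s' dropped",
                   cas, inchikey))
      inchikey <- NA_character_
    }
    syn <- xml2::xml_text(xml2::xml_find_all(node, d$chemical$synonym))
    chemicals[[cas]] <- list(
      cas = cas, name = name, synonyms = syn[nzchar(trimws(syn))],
      inchikey = inchikey, comptox = child_text(node, d$chemical$comptox))
  }

  # --- dangling references -----------------------------------------------------
  dangling <- data.frame(from = character(0), field = character(0),
                         to = character(0), stringsAsFactors = FALSE)
  note_dangling <- function(from, field, ids, known) {
    miss <- setdiff(ids, known)
    if (length(miss)) {
      dangling <<- rbind(dangling,
                         data.frame(from = from, field = field, to = miss,
                                    stringsAsFactors = FALSE))
    }
  }
  for (id in names(aops)) {
    note_dangling(paste0("aop:", id), "ke_ids", aops[[id]]$ke_ids, names(kes))
    note_dangling(paste0("aop:", id), "ker_ids", aops[[id]]$ker_ids, names(kers))
    note_dangling(paste0("aop:", id), "stressor_ids", aops[[id]]$stressor_ids,
                  names(stressors))
  }
  for (id in names(kers)) {
    note_dangling(paste0("ker:", id), "upstream_ke", kers[[id]]$upstream_ke,
                  names(kes))
    note_dangling(paste0("ker:", id), "downstream_ke", kers[[id]]$downstream_ke,
                  names(kes))
  }
  for (id in names(kes)) {
    note_dangling(paste0("ke:", id), "stressor_ids", kes[[id]]$stressor_ids,
                  names(stressors))
  }
  for (id in names(stressors)) {
    note_dangling(paste0("stressor:", id), "chemical_cas",
                  stressors[[id]]$chemical_cas, names(chemicals))
  }
  if (nrow(dangling)) {
    warn(sprintf("%d dangling reference(s): %s", nrow(dangling),
                 paste(utils::head(paste0(dangling$from, "->", dangling$to), 5L),
                       collapse = ", ")))
  }

  snapshot <- xml2::xml_attr(root, d$snapshot_attr)
  structure(list(aops = aops, kes = kes, kers = kers, stressors = stressors,
                 chemicals = chemicals, terms = terms,
                 snapshot_date = if (is.na(snapshot)) NA_character_ else snapshot,
                 source_path = path, warnings = warnings,
                 dangling = dangling, skipped = skipped),
            class = "aopwiki_model")
}

#' Summarize a knowledge model
#'
#' Per-collection entity counts plus the dangling-reference list, in
#' deterministic order.
#'
#' @param model An `aopwiki_model`.
#' @return Character vector of report lines (also printed by the `print`
#'   method).
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "aopwiki_model"))
  term_kinds <- vapply(model$terms, `[[`, character(1), "kind")
  lines <- c(
    sprintf("aops: %d", length(model$aops)),
    sprintf("key events: %d", length(model$kes)),
    sprintf("key event relationships: %d", length(model$kers)),
    sprintf("stressors: %d", length(model$stressors)),
    sprintf("chemicals: %d", length(model$chemicals)),
    sprintf("taxonomy terms: %d", sum(term_kinds == "taxonomy")),
    sprintf("cell terms: %d", sum(term_kinds == "cell")),
    sprintf("organ terms: %d", sum(term_kinds == "organ")),
    sprintf("ke component terms: %d",
            sum(term_kinds %in% c("process", "object", "action"))),
    sprintf("skipped entities: %d", sum(model$skipped)),
    sprintf("dangling references: %d", nrow(model$dangling)))
  if (nrow(model$dangling)) {
    dg <- model$dangling[order(model$dangling$from, model$dangling$to), ]
    lines <- c(lines, sprintf("  %s %s -> %s", dg$from, dg$field, dg$to))
  }
  lines
}

#' @export
print.aopwiki_model <- function(x, ...) {
  cat("AOP-Wiki knowledge model", if (!is.na(x$snapshot_date))
    sprintf("(snapshot %s)", x$snapshot_date) else "", "\n")
  cat(model_report(x), sep = "\n")
  invisible(x)
}
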