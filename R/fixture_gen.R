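# Seeded synthetic fixture generation: AOP-Wiki-style XML plus companion
# HGNC / PR-mapping / cross-reference tables, with a ground-truth record of
# every planted gene mention and identifier mapping (truth-first: plant,
# then record, so end-to-end tests are exact).

FILLER_WORDS <- c("the", "observed", "response", "in", "exposed", "tissue",
                  "shows", "a", "sustained", "increase", "of", "signalling",
                  "activity", "and", "downstream", "effects", "during",
                  "chronic", "exposure", "with", "marked", "changes")

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a small but structurally complete wiki: a handful of
#' AOPs with linear KE chains, stressors of which about two thirds carry
#' chemicals (matching the proportion reported for the live wiki), roughly
#' two planted gene mentions per scanned text field, and decoy tokens
#' (gene symbols embedded inside longer words) to exercise the matcher's
#' boundary rules.
#'
#' @param n_aops Number of AOPs.
#' @param kes_per_aop Key events per AOP (>= 2; first is the MIE, last the
#'   AO).
#' @param n_stressors Number of stressors.
#' @param chemical_fraction Fraction of stressors carrying a chemical.
#' @param genes_per_text Mean number of gene symbols planted per scanned
#'   text field (Poisson).
#' @param decoy_rate Probability of embedding a decoy (symbol inside a
#'   longer token) in each scanned field.
#' @param seed Integer seed; the same seed yields a byte-identical fixture.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_aops = 3L, kes_per_aop = 4L, n_stressors = 3L,
                           chemical_fraction = 0.63, genes_per_text = 2,
                           decoy_rate = 0.5, seed = 1L) {
  cfg <- list(n_aops = as.integer(n_aops),
              kes_per_aop = as.integer(kes_per_aop),
              n_stressors = as.integer(n_stressors),
              chemical_fraction = chemical_fraction,
              genes_per_text = genes_per_text,
              decoy_rate = decoy_rate, seed = as.integer(seed))
  if (cfg$n_aops < 0L || cfg$n_stressors < 0L) {
    stop("entity counts must be non-negative")
  }
  if (cfg$n_aops > 0L && cfg$kes_per_aop < 2L) {
    stop("kes_per_aop must be at least 2 (an MIE and an AO)")
  }
  if (cfg$chemical_fraction < 0 || cfg$chemical_fraction > 1 ||
      cfg$decoy_rate < 0 || cfg$decoy_rate > 1) {
    stop("fractions must lie in [0, 1]")
  }
  class(cfg) <- "fixture_config"
  cfg
}

#' Path to the bundled 50-symbol mini HGNC table
#' @return File path.
#' @export
hgnc_mini_path <- function() {
  system.file("extdata", "hgnc_mini.tsv", package = "aopwikirdf")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic fixture bundle
#'
#' Writes `aopwiki.xml`, `hgnc.tsv`, `promapping.tsv`, `xrefs.tsv` and
#' `truth.json` into `dir`. Gene symbols (drawn from the bundled mini HGNC
#' table) are planted into KE/KER text fields at recorded positions, decoy
#' tokens embed symbols inside longer words, and the returned truth object
#' enumerates every planted mention, decoy and identifier mapping.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
generate_fixture <- function(config = fixture_config(), dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  hgnc <- read_hgnc_table(hgnc_mini_path())
  symbols <- hgnc$symbol

  truth_matches <- list()
  truth_decoys <- character(0)
  note_match <- function(kind, id, field, syms) {
    if (!length(syms)) return()
    truth_matches[[length(truth_matches) + 1L]] <<- data.frame(
      entity_kind = kind, entity_id = as.character(id), field_name = field,
      symbol = syms, stringsAsFactors = FALSE)
  }
  # a text with `k` planted symbols and possibly one decoy token
  gene_text <- function(kind, id, field) {
    k <- stats::rpois(1L, config$genes_per_text)
    syms <- if (k > 0L) sample(symbols, min(k, length(symbols))) else character(0)
    words <- sample(FILLER_WORDS, 6L + stats::rpois(1L, 4L), replace = TRUE)
    for (s in syms) {
      at <- sample.int(length(words) + 1L, 1L)
      words <- append(words, s, after = at - 1L)
    }
    if (stats::runif(1L) < config$decoy_rate) {
      decoy <- paste0("pseudo", sample(symbols, 1L), "ase")
      truth_decoys <<- c(truth_decoys, decoy)
      words <- append(words, decoy, after = sample.int(length(words) + 1L, 1L))
    }
    note_match(kind, id, field, syms)
    paste(words, collapse = " ")
  }

  terms_pool <- list(
    process = c("GO:0008152", "MP:0001262", "MESH:D008108", "HP:0001392",
                "PCO:0000016", "NBO:0000313", "MI:0915", "VT:0010488"),
    object = c("PR:000008478", "PR:000016890", "FMA:7197", "CHEBI:35549"),
    cell = c("CL:0000000", "CL:0000182"),
    organ = c("UBERON:0000062", "UBERON:0002107"))

  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<data snapshot-date=\"2021-01-01\">")
  add <- function(...) lines <<- c(lines, paste0(...))

  n_kes <- config$n_aops * config$kes_per_aop
  ke_ids <- seq_len(n_kes) + 100L
  ker_ids <- integer(0)
  stressor_ids <- seq_len(config$n_stressors) + 200L
  chem_flags <- stats::runif(config$n_stressors) < config$chemical_fraction
  cas_numbers <- sprintf("%d-%02d-%d", 1000L + seq_len(config$n_stressors),
                         10L + seq_len(config$n_stressors) %% 80L,
                         seq_len(config$n_stressors) %% 10L)

  ker_counter <- 500L
  for (a in seq_len(config$n_aops)) {
    kes <- ke_ids[((a - 1L) * config$kes_per_aop + 1L):(a * config$kes_per_aop)]
    kers <- ker_counter + seq_len(length(kes) - 1L)
    ker_counter <- ker_counter + length(kers)
    ker_ids <- c(ker_ids, kers)
    stressor <- stressor_ids[(a - 1L) %% max(config$n_stressors, 1L) + 1L]
    add("  <aop id=\"", a, "\">")
    add("    <title>Synthetic pathway ", a, "</title>")
    add("    <creators>Fixture Generator</creators>")
    add("    <status>Under development</status>")
    add("    <created>2020-01-0", (a - 1L) %% 9L + 1L, "T10:00:00</created>")
    add("    <modified>2020-06-0", (a - 1L) %% 9L + 1L, "T10:00:00</modified>")
    add("    <key-events>")
    for (k in kes) add("      <key-event id=\"", k, "\"/>")
    add("    </key-events>")
    add("    <molecular-initiating-events>")
    add("      <key-event id=\"", kes[1L], "\"/>")
    add("    </molecular-initiating-events>")
    add("    <adverse-outcomes>")
    add("      <key-event id=\"", kes[length(kes)], "\"/>")
    add("    </adverse-outcomes>")
    add("    <key-event-relationships>")
    for (r in kers) add("      <key-event-relationship id=\"", r, "\"/>")
    add("    </key-event-relationships>")
    if (config$n_stressors > 0L) {
      add("    <stressors>")
      add("      <stressor id=\"", stressor, "\"/>")
      add("    </stressors>")
    }
    add("  </aop>")

    for (j in seq_along(kes)) {
      k <- kes[j]
      is_mie <- j == 1L
      is_ao <- j == length(kes)
      add("  <key-event id=\"", k, "\">")
      add("    <title>Synthetic key event ", k, "</title>")
      add("    <biological-organization-level>",
          c("Molecular", "Cellular", "Tissue", "Organ")[(j - 1L) %% 4L + 1L],
          "</biological-organization-level>")
      add("    <description>", xml_escape(gene_text("ke", k, "ke_description")),
          "</description>")
      if (is_mie) {
        add("    <mie-description>",
            xml_escape(gene_text("ke", k, "mie_ao_section")),
            "</mie-description>")
        if (config$n_stressors > 0L) {
          add("    <stressors>")
          add("      <stressor id=\"", stressor, "\"/>")
          add("    </stressors>")
        }
      }
      if (is_ao) {
        add("    <ao-description>",
            xml_escape(gene_text("ke", k, "mie_ao_section")),
            "</ao-description>")
      }
      add("    <cell-term term=\"", sample(terms_pool$cell, 1L), "\"/>")
      add("    <organ-term term=\"", sample(terms_pool$organ, 1L), "\"/>")
      add("    <biological-process term=\"",
          sample(terms_pool$process, 1L), "\"/>")
      add("    <biological-object term=\"",
          sample(terms_pool$object, 1L), "\"/>")
      add("    <biological-action text=\"WIKI:", j, "\"/>")
      add("    <taxonomy term=\"NCBITAXON:9606\" label=\"Homo sapiens\"/>")
      add("  </key-event>")
    }

    for (r in seq_along(kers)) {
      id <- kers[r]
      add("  <key-event-relationship id=\"", id, "\" upstream=\"", kes[r],
          "\" downstream=\"", kes[r + 1L], "\">")
      add("    <description>",
          xml_escape(gene_text("ker", id, "ker_description")),
          "</description>")
      add("    <biological-plausibility>",
          xml_escape(gene_text("ker", id, "biological_plausibility")),
          "</biological-plausibility>")
      add("    <empirical-support>",
          xml_escape(gene_text("ker", id, "empirical_support")),
          "</empirical-support>")
      add("  </key-event-relationship>")
    }
  }

  chem_cas <- character(0)
  for (s in seq_len(config$n_stressors)) {
    add("  <stressor id=\"", stressor_ids[s], "\">")
    add("    <title>Synthetic stressor ", stressor_ids[s], "</title>")
    if (chem_flags[s]) add("    <chemical cas=\"", cas_numbers[s], "\"/>")
    add("  </stressor>")
  }
  for (s in which(chem_flags)) {
    chem_cas <- c(chem_cas, cas_numbers[s])
    add("  <chemical cas=\"", cas_numbers[s], "\">")
    add("    <name>Synthetic chemical ", s, "</name>")
    add("  </chemical>")
  }
  add("</data>")

  paths <- c(xml = file.path(dir, "aopwiki.xml"),
             hgnc = file.path(dir, "hgnc.tsv"),
             pr = file.path(dir, "promapping.tsv"),
             xrefs = file.path(dir, "xrefs.tsv"),
             truth = file.path(dir, "truth.json"))
  writeLines(lines, paths[["xml"]], useBytes = TRUE)
  file.copy(hgnc_mini_path(), paths[["hgnc"]], overwrite = TRUE)

  pr_rows <- c("PR:000008478\tuniprot:Q9UKV0\texact",
               "PR:000008478\thgnc:HDAC9\texact",
               "PR:000016890\tuniprot:P06132\texact",
               "PR:000016890\thgnc:UROD\texact",
               "PR:000016890\tncbigene:7389\texact")
  writeLines(pr_rows, paths[["pr"]], useBytes = TRUE)

  matches <- if (length(truth_matches)) {
    unique(do.call(rbind, truth_matches))
  } else {
    data.frame(entity_kind = character(0), entity_id = character(0),
               field_name = character(0), symbol = character(0),
               stringsAsFactors = FALSE)
  }

  # xref table: every chemical maps to each chemical database; every planted
  # gene symbol maps to the three gene databases (ids derived from the HGNC
  # numeric id so the truth is reproducible from config + seed alone)
  xref_lines <- "source_db\tsource_id\ttarget_db\ttarget_id"
  for (cas in chem_cas) {
    stem <- gsub("-", "", cas, fixed = TRUE)
    for (db in chemical_target_dbs()) {
      xref_lines <- c(xref_lines,
                      paste("cas", cas, db, paste0("X", stem, "-", db),
                            sep = "\t"))
    }
  }
  planted <- sort(unique(matches$symbol), method = "radix")
  for (sym in planted) {
    num <- hgnc_numeric_id(hgnc$hgnc_id[hgnc$symbol == sym])
    xref_lines <- c(xref_lines,
                    paste("hgnc", sym, "ncbigene", num, sep = "\t"),
                    paste("hgnc", sym, "uniprot", sprintf("P%05d", num %% 90000L),
                          sep = "\t"),
                    paste("hgnc", sym, "ensembl", sprintf("ENSG%011d", num),
                          sep = "\t"))
  }
  writeLines(xref_lines, paths[["xrefs"]], useBytes = TRUE)

  truth <- list(
    config = unclass(config),
    counts = list(aops = config$n_aops, kes = n_kes,
                  kers = length(ker_ids),
                  stressors = config$n_stressors,
                  chemicals = length(chem_cas)),
    matches = matches,
    decoys = truth_decoys,
    chemical_cas = chem_cas,
    planted_symbols = planted,
    xrefs_per_chemical = length(chemical_target_dbs()),
    xrefs_per_gene = 3L)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' The canonical hand-written fixture bundle
#'
#' A fixture reproducing the exemplar entities of the RDF schema
#' documentation: AOP 38 with every schema field populated, KE 1502,
#' KER 865 (upstream KE 844, downstream KE 845, UROD mention), stressor 208
#' linked to `cas:25812-30-0`, and acetaminophen (`cas:103-90-2`) with
#' InChIKey, CompTox id and cross-references to all nine chemical
#' databases. Companion tables: the bundled mini HGNC table, a PR mapping
#' table and a static cross-reference table.
#'
#' @return Named character vector of paths (`xml`, `hgnc`, `pr`, `xrefs`).
#' @export
canonical_fixture <- function() {
  base <- system.file("extdata", "canonical", package = "aopwikirdf")
  c(xml = file.path(base, "aopwiki.xml"),
    hgnc = hgnc_mini_path(),
    pr = file.path(base, "promapping.tsv"),
    xrefs = file.path(base, "xrefs.tsv"))
}
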