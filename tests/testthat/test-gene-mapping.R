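mini_hgnc <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(c(list(hgnc_id = r[[1]], symbol = r[[2]], name = r[[3]]),
                    list(alias_symbol = if (length(r) > 3) r[[4]] else "",
                         alias_name = if (length(r) > 4) r[[5]] else "")),
                  stringsAsFactors = FALSE)
  }))
}

test_that("matching is boundary-aware: no partial-word hits", {
  dict <- build_symbol_dictionary(
    mini_hgnc(list("HGNC:12591", "UROD", "uroporphyrinogen decarboxylase"),
              list("HGNC:395", "ALAD", "aminolevulinate dehydratase")))
  expect_equal(scan_text("Reduced UROD enzyme activity", dict)$symbol, "UROD")
  expect_equal(nrow(scan_text("the sURODx complex", dict)), 0L)
  expect_equal(nrow(scan_text("SURODX", dict)), 0L)
  both <- scan_text("UROD/ALAD pathway", dict)
  expect_setequal(both$symbol, c("UROD", "ALAD"))
  expect_equal(nrow(scan_text("", dict)), 0L)
  expect_equal(nrow(scan_text(NA_character_, dict)), 0L)
  # spans index the matched substring (0-based, half-open)
  m <- scan_text("see UROD.", dict)
  expect_equal(substr("see UROD.", m$start + 1L, m$end), "UROD")
})

test_that("symbols match case-sensitively, full names case-insensitively", {
  dict <- build_symbol_dictionary(
    mini_hgnc(list("HGNC:11998", "TP53", "tumor protein p53")))
  expect_equal(scan_text("TP53 is mutated", dict)$symbol, "TP53")
  expect_equal(nrow(scan_text("tp53 is mutated", dict)), 0L)
  expect_equal(scan_text("Tumor Protein P53 accumulates", dict)$symbol, "TP53")
})

test_that("dictionary collisions resolve to the approved-symbol owner and are logged", {
  dict <- build_symbol_dictionary(
    mini_hgnc(list("HGNC:100", "MAA", "gene with approved symbol MAA"),
              list("HGNC:50", "OTHER", "other gene", "MAA", "")))
  hit <- scan_text("the MAA gene", dict)
  expect_equal(hit$hgnc_id, "HGNC:100")
  expect_equal(nrow(hit), 1L)
  expect_true("MAA" %in% attr(dict, "collisions")$form)
  # alias-vs-alias ties break to the lowest numeric HGNC id
  dict2 <- build_symbol_dictionary(
    mini_hgnc(list("HGNC:200", "GENEA", "gene a", "SHARED", ""),
              list("HGNC:30", "GENEB", "gene b", "SHARED", "")))
  expect_equal(scan_text("a SHARED alias", dict2)$hgnc_id, "HGNC:30")
})

test_that("minimum length and stop lists prune ambiguous forms", {
  tab <- mini_hgnc(list("HGNC:1", "AB", "short gene"),
                   list("HGNC:2", "LONGGENE", "long gene"))
  expect_equal(nrow(scan_text("AB LONGGENE", build_symbol_dictionary(tab))), 2L)
  expect_equal(scan_text("AB LONGGENE",
                         build_symbol_dictionary(tab, min_length = 3L))$symbol,
               "LONGGENE")
  expect_equal(scan_text("AB LONGGENE",
                         build_symbol_dictionary(tab, stop_list = "AB"))$symbol,
               "LONGGENE")
  expect_error(build_symbol_dictionary(data.frame(symbol = "X")), "missing")
})

test_that("scan_text agrees with the regex-lookaround oracle on random texts", {
  dict <- build_symbol_dictionary(hgnc_mini_path())
  set.seed(42)
  for (i in 1:20) {
    text <- random_scan_text(dict, target_nchar = 1500L)
    got <- scan_text(text, dict)
    want <- oracle_scan(text, dict)
    expect_identical(match_key(got), match_key(want))
  }
})

test_that("adding a dictionary entry never removes existing matches", {
  base_tab <- mini_hgnc(list("HGNC:1", "GENEA", "gene a"),
                        list("HGNC:2", "GENEB", "gene b"))
  bigger_tab <- rbind(base_tab,
                      mini_hgnc(list("HGNC:3", "GENEC", "gene c")))
  set.seed(11)
  small <- build_symbol_dictionary(base_tab)
  big <- build_symbol_dictionary(bigger_tab)
  for (i in 1:10) {
    text <- random_scan_text(big, target_nchar = 500L)
    expect_true(all(match_key(scan_text(text, small)) %in%
                      match_key(scan_text(text, big))))
  }
})

test_that("model scanning covers exactly the five gene-bearing text fields", {
  cc <- canonical_conversion()
  matches <- scan_model_genes(cc$model, cc$dict)
  expect_true(all(matches$field_name %in%
                    c("ke_description", "mie_ao_section", "ker_description",
                      "biological_plausibility", "empirical_support")))
  ker865 <- matches[matches$entity_kind == "ker" & matches$entity_id == "865", ]
  expect_setequal(unique(ker865$field_name),
                  c("ker_description", "biological_plausibility",
                    "empirical_support"))
  expect_true(all(ker865$symbol == "UROD"))
  ke844 <- matches[matches$entity_kind == "ke" & matches$entity_id == "844", ]
  expect_true("mie_ao_section" %in% ke844$field_name)
  expect_true("ALAD" %in% ke844$symbol)
})

test_that("PR terms map to gene/protein identifiers through the table", {
  pr <- read_pr_mapping(canonical_fixture()[["pr"]])
  xr <- map_pr_term("pr:000008478", pr)
  expect_setequal(xr$target_db, c("uniprot", "hgnc", "ncbigene"))
  expect_true("uniprot:Q9UKV0" %in% xr$target_id)
  expect_message(none <- map_pr_term("pr:000000001", pr), "no PR mapping")
  expect_equal(nrow(none), 0L)
  expect_error(map_pr_term("go:0008150", pr), "PRotein")
  # a row with only one target column filled yields a single xref
  tab <- data.frame(pr = "pr:000000002", target = "uniprot:P12345",
                    relation = "exact", stringsAsFactors = FALSE)
  expect_equal(nrow(map_pr_term("PR:000000002", tab)), 1L)
})
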