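test_that("collection sizes mirror the fixture element counts", {
  dir <- tempfile(); fx <- generate_fixture(fixture_config(seed = 7L), dir)
  model <- parse_aopwiki_xml(fx$paths[["xml"]])
  expect_equal(length(model$aops), fx$truth$counts$aops)
  expect_equal(length(model$kes), fx$truth$counts$kes)
  expect_equal(length(model$kers), fx$truth$counts$kers)
  expect_equal(length(model$stressors), fx$truth$counts$stressors)
  expect_equal(length(model$chemicals), fx$truth$counts$chemicals)
  expect_equal(sum(model$skipped), 0L)
})

test_that("parsing is deterministic", {
  dir <- tempfile(); fx <- generate_fixture(fixture_config(seed = 3L), dir)
  m1 <- parse_aopwiki_xml(fx$paths[["xml"]])
  m2 <- parse_aopwiki_xml(fx$paths[["xml"]])
  m1$source_path <- m2$source_path <- NULL
  expect_identical(m1, m2)
})

test_that("an empty document yields an empty model without error", {
  path <- tempfile(fileext = ".xml")
  writeLines("<data/>", path)
  model <- parse_aopwiki_xml(path)
  expect_equal(length(model$aops), 0L)
  expect_equal(length(model$kes), 0L)
  expect_equal(length(model$chemicals), 0L)
  expect_equal(nrow(model$dangling), 0L)
  lines <- model_report(model)
  expect_true(any(grepl("aops: 0", lines)))
  expect_true(any(grepl("chemicals: 0", lines)))
})

test_that("an MIE id outside the KE list is dropped with a warning", {
  path <- write_xml_fixture(c(
    '<aop id="1"><title>A</title>',
    '  <key-events><key-event id="10"/></key-events>',
    '  <molecular-initiating-events><key-event id="99"/></molecular-initiating-events>',
    '</aop>',
    '<key-event id="10"><title>KE</title></key-event>'))
  expect_warning(model <- parse_aopwiki_xml(path), "MIE id")
  expect_equal(model$aops[["1"]]$mie_ids, character(0))
  expect_equal(model$aops[["1"]]$ke_ids, "10")
})

test_that("entities without mandatory fields are skipped, never silently", {
  path <- write_xml_fixture(c(
    '<aop id="1"><title>A</title></aop>',
    '<aop id="2"></aop>',
    '<key-event id="5"><title>K</title></key-event>',
    '<key-event id=""><title>K2</title></key-event>'))
  warns <- character(0)
  model <- withCallingHandlers(parse_aopwiki_xml(path),
    warning = function(w) { warns <<- c(warns, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  # parsed + skipped-with-warning == entities present in the XML
  expect_equal(length(model$aops) + model$skipped[["aop"]], 2L)
  expect_equal(length(model$kes) + model$skipped[["ke"]], 2L)
  expect_equal(sum(model$skipped), 2L)
  expect_length(warns, 2L)
})

test_that("dangling references are collected and reported, not fatal", {
  path <- write_xml_fixture(c(
    '<key-event id="1"><title>up</title></key-event>',
    '<key-event-relationship id="7" upstream="1" downstream="999">',
    '</key-event-relationship>'))
  expect_warning(model <- parse_aopwiki_xml(path), "dangling")
  expect_equal(model$dangling$to, "999")
  expect_true(!is.null(model$kers[["7"]]))  # entry retained
  expect_true(any(grepl("ker:7 downstream_ke -> 999", model_report(model))))
})

test_that("self-loop KERs, bad CAS numbers and bad InChIKeys are rejected", {
  path <- write_xml_fixture(c(
    '<key-event id="1"><title>k</title></key-event>',
    '<key-event-relationship id="2" upstream="1" downstream="1"/>',
    '<stressor id="3"><title>s</title><chemical cas="notacas"/></stressor>',
    '<chemical cas="50-00-0"><name>Formaldehyde</name>',
    '<inchikey>TOOSHORT</inchikey></chemical>'))
  warns <- character(0)
  model <- withCallingHandlers(parse_aopwiki_xml(path),
    warning = function(w) { warns <<- c(warns, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  expect_null(model$kers[["2"]])
  expect_equal(model$stressors[["3"]]$chemical_cas, character(0))
  expect_true(is.na(model$chemicals[["50-00-0"]]$inchikey))
  expect_true(any(grepl("itself", warns)))
  expect_true(any(grepl("CAS", warns)))
  expect_true(any(grepl("InChIKey", warns)))
})

test_that("malformed XML fails with a parse error", {
  path <- tempfile(fileext = ".xml")
  writeLines("<data><aop id='1'>", path)
  expect_error(parse_aopwiki_xml(path))
  expect_error(parse_aopwiki_xml(tempfile()), "not found")
})

test_that("a dialect override file renames elements without code changes", {
  dpath <- tempfile(fileext = ".yaml")
  writeLines(c("aop:", "  element: pathway", "  title: name"), dpath)
  path <- write_xml_fixture(c('<pathway id="4"><name>Renamed</name></pathway>'))
  model <- parse_aopwiki_xml(path, aopwiki_dialect(dpath))
  expect_equal(model$aops[["4"]]$title, "Renamed")
})

test_that("term annotations are normalized and collected per kind", {
  path <- write_xml_fixture(c(
    '<key-event id="1"><title>k</title>',
    '  <cell-term term="CL:0000182" label="hepatocyte"/>',
    '  <biological-process term="GO:0008150"/>',
    '  <taxonomy text="WCS_9606"/>',
    '</key-event>'))
  model <- parse_aopwiki_xml(path)
  expect_equal(model$kes[["1"]]$cell_term, "cl:0000182")
  expect_equal(model$terms[["cl:0000182"]]$label, "hepatocyte")
  expect_equal(model$terms[["text:WCS_9606"]]$kind, "taxonomy")
  expect_true(is.na(model$terms[["text:WCS_9606"]]$curie))
})
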