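test_that("level detection reads namespace and level markers", {
  expect_identical(detect_level(write_mif(tiny_binary_doc())), "3.0")
  doc25 <- mif_downgrade(mif_use_case("j"))$document
  expect_identical(detect_level(write_mif(doc25)), "2.5")
  expect_identical(
    detect_level('<entrySet level="3" version="0"><entry/></entrySet>'),
    "3.0")
  expect_identical(
    detect_level('<entrySet level="2" version="5"><entry/></entrySet>'),
    "2.5")
  err <- tryCatch(
    detect_level('<entrySet xmlns="urn:something:else"><entry/></entrySet>'),
    psimif_namespace = function(e) e)
  expect_s3_class(err, "psimif_namespace")
  expect_match(conditionMessage(err), "urn:something:else")
  expect_error(detect_level("<banana/>"), class = "psimif_namespace")
  expect_error(detect_level("<entrySet><unclosed></entrySet>"),
               class = "psimif_parse")
})

test_that("one compact experiment definition is shared by its referencing interactions", {
  doc <- nary_doc(c(2L, 2L))          # two interactions, one experiment
  txt <- write_mif(doc, form = "compact")
  expect_identical(
    length(gregexpr("<experimentDescription ", txt, fixed = TRUE)[[1]]), 1L)
  rr <- read_mif(txt, strict = TRUE)
  entry <- rr$document$entries[[1]]
  expect_length(entry$experiments, 1L)
  refs <- lapply(entry$interactions, function(ia) ia$experiment_refs)
  expect_identical(refs[[1]], refs[[2]])
})

test_that("extended and compact forms parse to semantically equal documents", {
  for (case in mif_use_cases()) {
    doc <- mif_use_case(case)
    compact <- read_mif(write_mif(doc, form = "compact"), strict = TRUE)
    extended <- read_mif(write_mif(doc, form = "extended"), strict = TRUE)
    expect_semantically_equal(compact$document, extended$document)
  }
})

test_that("negative promoter coordinates survive parsing exactly", {
  doc <- mif_use_case("a")
  rr <- read_mif(write_mif(doc), strict = TRUE)
  feats <- rr$document$entries[[1]]$interactions[[1]]$participants[[1]]$features
  r <- feats[[1]]$ranges[[1]]
  expect_identical(r$begin, mif_pos_exact(-2000L))
  expect_identical(r$end, mif_pos_exact(-1L))
})

test_that("repeated feature detection methods keep document order", {
  doc <- mif_use_case("c")
  rr <- read_mif(write_mif(doc), strict = TRUE)
  f <- rr$document$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]
  expect_length(f$detection_methods, 2L)
  expect_identical(f$detection_methods[[1]]$mi_accession, "MI:0421")
  expect_identical(f$detection_methods[[2]]$mi_accession, "MI:0943")
})

test_that("a bibref can hold both an xref and publication attributes", {
  doc <- mif_use_case("k")
  txt <- write_mif(doc)
  node <- xml2::read_xml(txt)
  xml2::xml_ns_strip(node)
  bib <- xml2::xml_find_first(node, "//experimentDescription/bibref")
  expect_false(inherits(xml2::xml_find_first(bib, "./xref"), "xml_missing"))
  expect_false(inherits(xml2::xml_find_first(bib, "./attributeList"),
                        "xml_missing"))
  rr <- read_mif(txt, strict = TRUE)
  b <- rr$document$entries[[1]]$experiments[[1]]$bibref
  expect_identical(b$xref$primary$id, "26919541")
  expect_length(b$attributes, 2L)
})

test_that("cooperative effects round-trip with kind, outcome and affected refs", {
  doc <- mif_use_case("h")
  for (form in c("compact", "extended")) {
    rr <- read_mif(write_mif(doc, form = form), strict = TRUE)
    abs_idx <- which(vapply(rr$document$entries[[1]]$interactions,
                            inherits, logical(1),
                            "mif_abstract_interaction"))
    ab <- rr$document$entries[[1]]$interactions[[abs_idx]]
    expect_length(ab$cooperative_effects, 1L)
    eff <- ab$cooperative_effects[[1]]
    expect_identical(eff$kind, "allostery")
    expect_identical(eff$outcome$short_label, "positive cooperative effect")
    expect_length(eff$affected_refs, 1L)
    expect_identical(eff$effector$kind, "molecule")
    expect_semantically_equal(rr$document, mif_normalize(doc))
  }
})

test_that("an empty one-entry document round-trips minimally", {
  doc <- mif_document(mif_entry())
  txt <- write_mif(doc)
  rr <- read_mif(txt, strict = TRUE)
  expect_semantically_equal(rr$document, doc)
  expect_length(mif_check_structure(txt), 0L)
})

test_that("round trip holds for generated documents in both forms", {
  for (s in c(101L, 202L, 303L)) {
    d <- mif_generate(mif_generator_spec(seed = s))
    nd <- mif_normalize(d)
    for (form in c("compact", "extended")) {
      rr <- read_mif(write_mif(d, form = form), strict = TRUE)
      expect_semantically_equal(rr$document, nd)
    }
  }
})

test_that("decimal lexical forms survive a round trip unchanged", {
  doc <- mif_use_case("j")
  txt1 <- write_mif(doc)
  expect_match(txt1, '<stoichiometry value="2.0"/>', fixed = TRUE)
  txt2 <- write_mif(read_mif(txt1, strict = TRUE)$document)
  expect_match(txt2, '<stoichiometry value="2.0"/>', fixed = TRUE)
  expect_match(txt2, 'minValue="2" maxValue="4"', fixed = TRUE)

  docE <- mif_use_case("e")
  txtE <- write_mif(read_mif(write_mif(docE), strict = TRUE)$document)
  expect_match(txtE, 'factor="3.1"', fixed = TRUE)
  expect_match(txtE, 'factor="2.4"', fixed = TRUE)
})

test_that("writing a 2.5 document with 3.0-only content is refused", {
  doc <- mif_use_case("j")
  doc$level <- "2.5"
  err <- tryCatch(write_mif(doc), psimif_level = function(e) e)
  expect_s3_class(err, "psimif_level")
  expect_match(conditionMessage(err), "mif_downgrade")
  expect_match(conditionMessage(err), "STOICHIOMETRY_ELEMENT")
})

test_that("gzip streams are sniffed and read transparently", {
  doc <- tiny_binary_doc()
  path <- withr::local_tempfile(fileext = ".xml.gz")
  write_mif(doc, path)
  expect_identical(detect_level(path), "3.0")
  rr <- read_mif(path, strict = TRUE)
  expect_semantically_equal(rr$document, doc)
})

test_that("strict mode makes dangling references fatal; lax mode drops them", {
  doc <- tiny_binary_doc()
  doc$entries[[1]]$interactions[[1]]$experiment_refs <- c(1L, 999L)
  txt <- write_mif(doc)
  strict <- read_mif(txt, strict = TRUE)
  expect_null(strict$document)
  expect_identical(strict$findings[[1]]$code, "DANGLING_REF")
  expect_match(strict$findings[[1]]$message, "999")
  lax <- read_mif(txt, strict = FALSE)
  expect_identical(lax$document$entries[[1]]$interactions[[1]]$experiment_refs,
                   1L)
  expect_length(lax$findings, 1L)
})

test_that("serialization is byte-deterministic", {
  d <- mif_generate(mif_generator_spec(seed = 77L))
  expect_identical(write_mif(d), write_mif(d))
  expect_identical(write_mif(d, form = "extended"),
                   write_mif(d, form = "extended"))
})
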