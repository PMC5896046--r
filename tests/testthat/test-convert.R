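test_that("a document without 3.0-only content downgrades losslessly", {
  doc <- tiny_binary_doc()
  res <- mif_downgrade(doc)
  expect_length(res$report$items, 0L)
  expect_identical(res$document$level, "2.5")
  expect_semantically_equal(mif_upgrade(res$document), doc)
})

test_that("downgrade loss reports match each fixture's expected manifest exactly", {
  for (case in mif_use_cases()) {
    doc <- mif_use_case(case)
    manifest <- attr(doc, "loss_manifest")
    got <- mif_loss_categories(mif_downgrade(doc)$report)
    expect_identical(got[order(names(got))],
                     manifest[order(names(manifest))],
                     label = sprintf("case %s manifest", case))
  }
})

test_that("an abstract complex downgrades to an interaction inferred by curator", {
  res <- mif_downgrade(mif_use_case("g"))
  entry <- res$document$entries[[1]]
  expect_length(entry$interactions, 1L)
  ia <- entry$interactions[[1]]
  expect_s3_class(ia, "mif_interaction")
  expect_length(ia$experiment_refs, 1L)
  synth <- Filter(function(ex) ex$id == ia$experiment_refs, entry$experiments)
  expect_length(synth, 1L)
  expect_identical(synth[[1]]$interaction_detection_method$mi_accession,
                   "MI:0364")
  # the abstract interaction's own xref doubles as the synthesized bibref
  expect_identical(synth[[1]]$bibref$xref$primary$id, "CPX-70001")
})

test_that("candidate sets collapse to a molecule-set interactor with candidate xrefs", {
  res <- mif_downgrade(mif_use_case("i"))
  entry <- res$document$entries[[1]]
  p <- entry$interactions[[1]]$participants[[1]]
  expect_identical(p$entity$kind, "interactor_ref")
  placeholder <- Filter(function(it) it$id == p$entity$ref, entry$interactors)
  expect_length(placeholder, 1L)
  expect_identical(placeholder[[1]]$interactor_type$mi_accession, "MI:1305")
  cand_ids <- c(placeholder[[1]]$xref$primary$id,
                vapply(Filter(function(s) s$db == "psimif-candidate",
                              placeholder[[1]]$xref$secondary),
                       function(s) s$id, character(1)))
  expect_setequal(cand_ids, c("CALM1", "CALM2", "CALM3"))
})

test_that("downgraded stoichiometry and feature constructs surface as attributes", {
  res <- mif_downgrade(mif_use_case("j"))
  ps <- res$document$entries[[1]]$interactions[[1]]$participants
  stoich_attrs <- unlist(lapply(ps, function(p) {
    vapply(Filter(function(a) a$name == "psimi3:stoichiometry", p$attributes),
           function(a) a$value, character(1))
  }))
  expect_setequal(stoich_attrs, c("mean|2.0", "range|2|4"))

  res_e <- mif_downgrade(mif_use_case("e"))
  ia <- res_e$document$entries[[1]]$interactions[[1]]
  # mutant kd joins the wild-type kd at the interaction level
  expect_length(ia$parameters, 2L)
  feats <- unlist(lapply(ia$participants, function(p) p$features),
                  recursive = FALSE)
  expect_true(all(vapply(feats, function(f) length(f$parameters) == 0L,
                         logical(1))))
})

test_that("upgrade with promotion inverts the downgrade on every fixture", {
  for (case in mif_use_cases()) {
    doc <- mif_use_case(case)
    res <- mif_downgrade(doc)
    promoted <- mif_upgrade(res$document, promote = TRUE)
    expect_identical(promoted$level, "3.0")
    expect_semantically_equal(promoted, mif_normalize(doc))
  }
})

test_that("upgrade without promotion lifts the level and invents nothing", {
  doc25 <- mif_downgrade(mif_use_case("j"))$document
  up <- mif_upgrade(doc25)
  expect_identical(up$level, "3.0")
  same <- doc25
  same$level <- "3.0"
  expect_semantically_equal(up, same)
})

test_that("downgrade after upgrade of a plain 2.5 document is the identity", {
  doc25 <- mif_downgrade(tiny_binary_doc())$document
  res <- mif_downgrade(mif_upgrade(doc25))
  expect_length(res$report$items, 0L)
  expect_semantically_equal(res$document, doc25)
})

test_that("every removed construct appears in the loss report exactly once", {
  # conservation, property-tested over seeded random documents: an
  # independent scan of the 3.0-only constructs must agree with the
  # report's category multiset
  for (s in c(11L, 23L, 37L, 58L)) {
    d <- mif_generate(mif_generator_spec(seed = s))
    scan <- psimif:::scan_30_constructs(d)
    scan_cats <- sort(vapply(scan, function(it) it$category, character(1)))
    rep_cats <- sort(vapply(mif_downgrade(d)$report$items,
                            function(it) it$category, character(1)))
    expect_identical(rep_cats, scan_cats)
    # and the promoted round trip still holds
    expect_semantically_equal(
      mif_upgrade(mif_downgrade(d)$document, promote = TRUE),
      mif_normalize(d))
  }
})

test_that("downgrade is total on validator-clean generated input", {
  for (s in c(5L, 6L)) {
    d <- mif_generate(mif_generator_spec(seed = s))
    expect_identical(mif_n_findings(mif_validate(d), "error"), 0L)
    expect_error(mif_downgrade(d), NA)
    expect_length(mif_check_structure(write_mif(mif_downgrade(d)$document)),
                  0L)
  }
})
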