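test_that("constructors enforce the type invariants", {
  expect_error(mif_cv(), "short_label or an mi_accession")
  expect_error(mif_cv("x", mi_accession = "MI:12"), "4 digits")
  expect_error(mif_cv("x", mi_accession = "MI:00001"), "4 digits")
  expect_silent(mif_cv(mi_accession = "MI:0326"))

  expect_error(mif_xref(mif_dbref("db", "1"), secondary = list("no")),
               "mif_dbref")
  expect_error(mif_dbref("", "1"), "non-empty")
  expect_error(mif_attribute(""), "non-empty")
  expect_error(mif_bibref(), "xref or at least one attribute")
  expect_error(mif_organism(0), "must not be 0")
  expect_silent(mif_organism(-1))   # in-vitro sentinel

  expect_error(mif_parameter("kd", factor = Inf), "finite")
  expect_error(mif_parameter("kd", factor = 1, base = 1L), ">= 2")
  expect_error(mif_variable_parameter("", list()), "non-empty")
  expect_error(mif_variable_parameter("conc", list()), "at least one value")

  expect_error(mif_pos_interval(5, 2), "<=")
  expect_error(mif_resulting_sequence(original = "A"), "xref")
  expect_silent(mif_resulting_sequence(xref = mif_xref(mif_dbref("e", "s"))))

  expect_error(mif_stoich_range(4, 2), "<=")
  expect_error(mif_stoich_mean(-1), ">= 0")

  expect_error(mif_entity(), "exactly one entity branch")
  expect_error(mif_entity(interactor_ref = 1, interaction_ref = 2),
               "exactly one entity branch")
  expect_error(mif_candidate_set(mif_cv("set"), list()),
               "at least one candidate")
  expect_error(mif_feature(1, ranges = list()), "at least one range")
  expect_error(mif_document(list()), "at least one entry")
  expect_error(mif_document(mif_entry(), level = "1.0"), "2.5")
})

test_that("the reference graph of a valid entry is closed", {
  doc <- tiny_binary_doc()
  entry <- doc$entries[[1]]
  defined <- psimif:::entry_defined_ids(entry)
  referenced <- vapply(psimif:::entry_references(entry),
                       function(r) r$id, integer(1))
  expect_true(all(referenced %in% defined))
  expect_identical(sort(defined), 1:6)
})

test_that("semantic equality holds for identity and id renumbering", {
  d1 <- mif_document(mif_entry())
  d2 <- mif_document(mif_entry())
  expect_true(mif_semantic_equal(d1, d2)$equal)

  doc <- tiny_binary_doc()
  shifted <- psimif:::map_ids(doc, function(v) as.integer(v) + 100L)
  class(shifted) <- "mif_document"
  expect_true(mif_semantic_equal(doc, shifted)$equal)
})

test_that("a stoichiometry change yields exactly one diff at the participant path", {
  # independent oracle: a field-by-field walk of the two object graphs
  # finds the single differing field (stoichiometry kind of participant 2)
  doc_mean <- tiny_binary_doc()
  doc_mean$entries[[1]]$interactions[[1]]$participants[[2]]$stoichiometry <-
    mif_stoich_mean(2)
  doc_range <- tiny_binary_doc()
  doc_range$entries[[1]]$interactions[[1]]$participants[[2]]$stoichiometry <-
    mif_stoich_range(2, 4)
  eq <- mif_semantic_equal(doc_mean, doc_range)
  expect_false(eq$equal)
  paths <- vapply(eq$diffs, function(d) d$path, character(1))
  expect_true(all(grepl("participants\\[2\\]/stoichiometry", paths)))
  expect_length(unique(sub("/stoichiometry.*$", "", paths)), 1L)
})

test_that("semantic_equal raises a classed error on dangling references", {
  doc <- tiny_binary_doc()
  doc$entries[[1]]$interactions[[1]]$experiment_refs <- 999L
  expect_error(mif_semantic_equal(doc, tiny_binary_doc()),
               class = "psimif_unresolved")
  expect_error(mif_semantic_equal(doc, tiny_binary_doc()), "999")
})

test_that("normalize renumbers densely, is idempotent and drops nothing", {
  doc <- tiny_binary_doc()
  shifted <- psimif:::map_ids(doc, function(v) as.integer(v) * 7L + 2L)
  class(shifted) <- "mif_document"
  norm <- mif_normalize(shifted)
  expect_identical(sort(psimif:::entry_defined_ids(norm$entries[[1]])), 1:6)
  expect_true(mif_semantic_equal(norm, doc)$equal)

  expect_identical(write_mif(mif_normalize(norm)), write_mif(norm))

  # duplicated attribute entries are retained, never deduplicated
  doc$entries[[1]]$attributes <- list(mif_attribute("comment", "x"),
                                      mif_attribute("comment", "x"))
  expect_length(mif_normalize(doc)$entries[[1]]$attributes, 2L)
})

test_that("semantic_equal is an equivalence relation on normalized documents", {
  docs <- lapply(1:6, function(s) mif_generate(mif_generator_spec(seed = s)))
  for (d in docs) {
    expect_true(mif_semantic_equal(d, d)$equal)         # reflexive
  }
  for (i in 1:3) {
    a <- docs[[i]]
    b <- psimif:::map_ids(a, function(v) as.integer(v) + 50L)
    class(b) <- "mif_document"
    c_ <- psimif:::map_ids(b, function(v) as.integer(v) + 13L)
    class(c_) <- "mif_document"
    expect_identical(mif_semantic_equal(a, b)$equal,
                     mif_semantic_equal(b, a)$equal)     # symmetric
    expect_true(mif_semantic_equal(a, b)$equal &&
                  mif_semantic_equal(b, c_)$equal &&
                  mif_semantic_equal(a, c_)$equal)       # transitive
  }
  # and distinct documents do compare different
  expect_false(mif_semantic_equal(docs[[1]], docs[[2]])$equal)
})
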