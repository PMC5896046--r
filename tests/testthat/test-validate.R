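# Mutation-kill suite: each finding code has a fixture mutated in exactly
# one place that triggers that code and no errors of any other code.

mutations <- list(
  ID_DUPLICATE = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactors[[2]]$id <- 2L
    doc$entries[[1]]$interactions[[1]]$participants[[2]]$entity$ref <- 2L
    doc
  },
  DANGLING_REF = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$experiment_refs <- 999L
    doc
  },
  NO_PARTICIPANTS = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$participants <- list()
    doc
  },
  EVIDENCE_NO_EXPERIMENT = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$experiment_refs <- integer(0)
    doc
  },
  ABSTRACT_HAS_EXPERIMENT = function() {
    doc <- mif_use_case("g")
    ex <- mif_experiment(90L, mif_bibref(mif_xref(mif_dbref("pubmed", "9"))),
                         mif_cv("two hybrid", mi_accession = "MI:0018"))
    doc$entries[[1]]$experiments <- list(ex)
    doc$entries[[1]]$interactions[[1]]$experiment_refs <- 90L
    doc
  },
  EMPTY_RANGES = function() {
    doc <- mif_use_case("d")
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]$ranges <-
      list()
    doc
  },
  RESSEQ_EMPTY = function() {
    doc <- mif_use_case("b")
    f <- doc$entries[[1]]$interactions[[1]]$participants[[2]]$features[[1]]
    f$ranges[[1]]$resulting_sequence <-
      structure(list(original = NULL, new = NULL, xref = NULL),
                class = "mif_resulting_sequence")
    doc$entries[[1]]$interactions[[1]]$participants[[2]]$features[[1]] <- f
    doc
  },
  RESSEQ_BAD_SEQUENCE = function() {
    doc <- mif_use_case("b")
    doc$entries[[1]]$interactions[[1]]$participants[[2]]$features[[1]]$
      ranges[[1]]$resulting_sequence$new <- "R9!"
    doc
  },
  RANGE_INVERTED = function() {
    doc <- mif_use_case("d")
    f <- doc$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]
    f$ranges[[1]]$begin <- mif_pos_exact(50L)
    f$ranges[[1]]$end <- mif_pos_exact(10L)
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]] <- f
    doc
  },
  STOICH_RANGE_INVERTED = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$stoichiometry <-
      structure(list(kind = "range", min_value = 4, max_value = 2,
                     min_lexical = NULL, max_lexical = NULL),
                class = "mif_stoichiometry")
    doc
  },
  STOICH_NEGATIVE = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$stoichiometry <-
      structure(list(kind = "mean", value = -2, value_lexical = NULL),
                class = "mif_stoichiometry")
    doc
  },
  FEATURE_ROLE_NO_ACCESSION = function() {
    doc <- mif_use_case("d")
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]$
      feature_role <- mif_cv("prerequisite-ptm")
    doc
  },
  ORDER_NEGATIVE = function() {
    doc <- mif_use_case("f")
    doc$entries[[1]]$experiments[[1]]$variable_parameters[[1]]$
      values[[2]]$order <- -1L
    doc
  },
  POSITION_ZERO = function() {
    doc <- mif_use_case("a")
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]$
      ranges[[1]]$end <- mif_pos_exact(0L)
    doc
  },
  NEG_POS_ON_PROTEIN = function() {
    doc <- tiny_binary_doc()
    f <- mif_feature(7L, ranges = list(mif_feature_range(
      mif_cv("certain", mi_accession = "MI:0335"), mif_pos_exact(-10L),
      mif_cv("certain", mi_accession = "MI:0335"), mif_pos_exact(-2L))))
    doc$entries[[1]]$interactions[[1]]$participants[[1]]$features <- list(f)
    doc
  },
  ORDER_DUPLICATE = function() {
    doc <- mif_use_case("f")
    doc$entries[[1]]$experiments[[1]]$variable_parameters[[1]]$
      values[[2]]$order <- 1L
    doc
  },
  MIXED_INTERACTION_KINDS = function() {
    mif_use_case("h")          # evidence + abstract in one interaction list
  },
  CV_BAD_ACCESSION = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactors[[1]]$interactor_type$mi_accession <- "MI:33"
    doc
  },
  CV_UNKNOWN = function() {
    doc <- tiny_binary_doc()
    doc$entries[[1]]$interactions[[1]]$interaction_types <-
      list(mif_cv("exotic method", mi_accession = "MI:9999"))
    doc
  }
)

test_that("the finding-code list is closed and covers at least 12 codes", {
  codes <- mif_finding_codes()
  expect_gte(nrow(codes), 12L)
  expect_setequal(names(mutations), codes$code)
  expect_true(all(codes$severity %in% c("error", "warning")))
})

test_that("each single-mutation fixture triggers exactly its own code", {
  codes <- mif_finding_codes()
  for (code in names(mutations)) {
    doc <- mutations[[code]]()
    findings <- mif_validate(doc, profile = "cv")
    expect_true(code %in% all_codes(findings),
                label = sprintf("%s triggered", code))
    sev <- codes$severity[codes$code == code]
    other_errors <- setdiff(error_codes(findings), code)
    expect_length(other_errors, 0L)
    if (sev == "error") {
      expect_identical(error_codes(findings), code)
    }
  }
})

test_that("unmutated golden fixtures produce zero errors", {
  for (case in mif_use_cases()) {
    findings <- mif_validate(mif_use_case(case), profile = "cv")
    expect_identical(mif_n_findings(findings, "error"), 0L,
                     label = sprintf("case %s error count", case))
  }
})

test_that("validation is pure and deterministic", {
  doc <- mutations$ORDER_DUPLICATE()
  f1 <- mif_validate(doc, profile = "cv")
  f2 <- mif_validate(doc, profile = "cv")
  expect_identical(mif_findings_json(f1), mif_findings_json(f2))
  expect_true(all(nzchar(vapply(f1, function(f) f$path, character(1)))))
})

test_that("profiles nest and individual codes can be suppressed", {
  doc <- mutations$CV_UNKNOWN()
  expect_false("CV_UNKNOWN" %in%
                 all_codes(mif_validate(doc, profile = "semantic")))
  expect_true("CV_UNKNOWN" %in% all_codes(mif_validate(doc, profile = "cv")))
  expect_false("CV_UNKNOWN" %in%
                 all_codes(mif_validate(doc, profile = "cv",
                                        suppress = "CV_UNKNOWN")))
})

test_that("the embedded CV store resolves the core accessions", {
  store <- mif_cv_store()
  for (acc in c("MI:0442", "MI:0367", "MI:0363", "MI:0364", "MI:0638",
                "MI:0925", "MI:0326", "MI:0904")) {
    expect_true(mif_cv_known(store, acc), label = acc)
  }
  expect_false(mif_cv_known(store, "MI:9999"))
  expect_null(mif_cv_lookup(store, "MI:9999"))
  expect_identical(mif_cv_lookup(store, "MI:0326")$label, "protein")
  expect_identical(mif_cv_lookup(store, "MI:0326")$parents, "MI:0313")
})

test_that("OBO loading merges over the embedded store, file winning", {
  base_n <- length(ls(mif_cv_store()$index))

  empty <- mif_load_cv("")
  expect_identical(length(ls(empty$index)), base_n)

  one <- mif_load_cv("[Term]\nid: MI:0000\nname: root\n\n[Term]\nid: MI:7777\nname: brand new term\nis_a: MI:0001 ! detection\n")
  expect_identical(length(ls(one$index)), base_n + 1L)
  expect_identical(mif_cv_lookup(one, "MI:7777")$label, "brand new term")
  expect_identical(mif_cv_lookup(one, "MI:7777")$parents, "MI:0001")

  redef <- mif_load_cv("[Term]\nid: MI:0326\nname: polypeptide chain\n")
  expect_identical(length(ls(redef$index)), base_n)
  expect_identical(mif_cv_lookup(redef, "MI:0326")$label, "polypeptide chain")

  skipped <- mif_load_cv("[Term]\nname: no id here\n")
  expect_identical(length(ls(skipped$index)), base_n)
  fnd <- attr(skipped, "findings")
  expect_length(fnd, 1L)
  expect_identical(fnd[[1]]$code, "OBO_STANZA_SKIPPED")
})
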