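test_that("every golden 3.0 serialization passes the structural check", {
  for (case in mif_use_cases()) {
    for (form in c("compact", "extended")) {
      violations <- mif_check_structure(write_mif(mif_use_case(case),
                                                  form = form))
      expect_length(violations, 0L)
    }
  }
})

test_that("downgraded documents conform to the 2.5 grammar", {
  for (case in mif_use_cases()) {
    doc25 <- mif_downgrade(mif_use_case(case))$document
    violations <- mif_check_structure(write_mif(doc25))
    expect_length(violations, 0L)
    expect_identical(detect_level(write_mif(doc25)), "2.5")
  }
})

test_that("3.0-only elements are rejected at level 2.5", {
  txt <- write_mif(mif_use_case("j"))          # stoichiometry elements
  violations <- mif_check_structure(txt, level = "2.5")
  expect_gt(length(violations), 0L)
  expect_true(any(grepl("stoichiometry", violations)))

  txt_g <- write_mif(mif_use_case("g"))        # abstractInteraction
  v_g <- mif_check_structure(txt_g, level = "2.5")
  expect_true(any(grepl("abstractInteraction", v_g)))

  txt_a <- write_mif(mif_use_case("a"))        # negative positions
  v_a <- mif_check_structure(txt_a, level = "2.5")
  expect_true(any(grepl("unsigned|not allowed", v_a)))
})

test_that("grammar violations inside a 3.0 document are reported with paths", {
  broken <- '<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0">
  <entry>
    <interactionList>
      <interaction id="1">
        <participantList>
          <participant id="2"><banana/></participant>
        </participantList>
      </interaction>
    </interactionList>
  </entry>
</entrySet>'
  violations <- mif_check_structure(broken)
  expect_true(any(grepl("banana", violations)))
  expect_true(any(grepl("requires between 1 and 1", violations)))
  expect_true(all(grepl("^/entrySet", violations)))

  no_bib <- '<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0">
  <entry>
    <experimentList>
      <experimentDescription id="1">
        <interactionDetectionMethod><names><shortLabel>x</shortLabel></names></interactionDetectionMethod>
      </experimentDescription>
    </experimentList>
  </entry>
</entrySet>'
  expect_true(any(grepl("bibref", mif_check_structure(no_bib))))
})

test_that("a 2.5 bibref must choose between xref and attributes", {
  doc <- mif_use_case("k")          # bibref with both halves
  txt <- write_mif(doc)
  expect_true(any(grepl("choice between xref and attributeList",
                        mif_check_structure(txt, level = "2.5"))))
  expect_length(mif_check_structure(txt, level = "3.0"), 0L)
  # after the downgrade the split satisfies the 2.5 grammar
  txt25 <- write_mif(mif_downgrade(doc)$document)
  expect_length(mif_check_structure(txt25), 0L)
})
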