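test_that("binary expansion follows the spoke model", {
  two <- nary_doc(2L)$entries[[1]]$interactions[[1]]
  pairs <- mif_expand_binary(two)
  expect_length(pairs, 1L)
  expect_identical(pairs[[1]]$expansion, "none")

  five <- nary_doc(5L)$entries[[1]]$interactions[[1]]
  pairs5 <- mif_expand_binary(five)
  expect_length(pairs5, 4L)
  bait_id <- five$participants[[1]]$id
  expect_true(all(vapply(pairs5, function(bp) bp$a$id == bait_id,
                         logical(1))))
  expect_true(all(vapply(pairs5, function(bp) bp$expansion == "spoke",
                         logical(1))))

  # no bait: the hub is the first participant, deterministically ordered
  three <- nary_doc(3L, with_bait = FALSE)$entries[[1]]$interactions[[1]]
  pairs3 <- mif_expand_binary(three)
  expect_length(pairs3, 2L)
  hub <- three$participants[[1]]$id
  expect_identical(vapply(pairs3, function(bp) bp$a$id, integer(1)),
                   c(hub, hub))
  expect_identical(vapply(pairs3, function(bp) bp$b$id, integer(1)),
                   c(three$participants[[2]]$id, three$participants[[3]]$id))
})

test_that("a single intramolecular participant yields one self-pair", {
  doc <- nary_doc(1L)
  doc$entries[[1]]$interactions[[1]]$intra_molecular <- TRUE
  pairs <- mif_expand_binary(doc$entries[[1]]$interactions[[1]])
  expect_length(pairs, 1L)
  expect_identical(pairs[[1]]$a$id, pairs[[1]]$b$id)
})

test_that("zero participants is an error", {
  ia <- tiny_binary_doc()$entries[[1]]$interactions[[1]]
  ia$participants <- list()
  expect_error(mif_expand_binary(ia), class = "psimif_expand")
})

test_that("an empty document exports a header-comment line only", {
  lines <- write_mitab(mif_document(mif_entry()))
  expect_length(lines, 1L)
  expect_match(lines[1], "^#")
  expect_length(strsplit(lines[1], "\t", fixed = TRUE)[[1]], 42L)
})

test_that("row counts follow the expansion arithmetic and cells stay clean", {
  doc <- nary_doc(c(2L, 3L, 5L))
  lines <- write_mitab(doc)
  expect_length(lines, 1L + (1L + 2L + 4L))
  rows <- lines[-1]
  for (row in rows) {
    expect_length(strsplit(row, "\t", fixed = TRUE)[[1]], 42L)
  }
  # the three spoke rows of the 4-participant-plus interactions share the
  # source interaction identifier
  cells <- lapply(rows, function(r) strsplit(r, "\t", fixed = TRUE)[[1]])
  ids <- vapply(cells, `[[`, character(1), 14L)
  expect_length(unique(ids[2:3]), 1L)
  expect_length(unique(ids[4:6]), 1L)
})

test_that("free text never leaks tabs, pipes or newlines into cells", {
  doc <- tiny_binary_doc()
  doc$entries[[1]]$interactions[[1]]$attributes <- list(
    mif_attribute("comment", "evil\tvalue|with\nbreaks"))
  lines <- write_mitab(doc)
  row <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expect_length(row, 42L)
  expect_match(row[28], "comment:evil value with breaks", fixed = TRUE)
})

test_that("abstract interactions are skipped with a notice", {
  doc <- mif_use_case("h")
  expect_message(lines <- write_mitab(doc), "skipping abstract interaction")
  expect_length(lines, 2L)    # header + one evidence row
})

test_that("negative interactions export with the negative column set", {
  doc <- tiny_binary_doc()
  doc$entries[[1]]$interactions[[1]]$negative <- TRUE
  row <- strsplit(write_mitab(doc)[2], "\t", fixed = TRUE)[[1]]
  expect_identical(row[36], "true")
})

test_that("identifier, feature and stoichiometry columns carry model content", {
  doc <- mif_use_case("j")
  row <- strsplit(write_mitab(doc)[2], "\t", fixed = TRUE)[[1]]
  expect_identical(row[1], "uniprotkb:X00001")
  expect_identical(row[2], "uniprotkb:X00002")
  expect_identical(row[39], "2")
  expect_identical(row[40], "2-4")
  expect_match(row[16], "-", fixed = TRUE)     # binary: no expansion

  doc_a <- mif_use_case("a")
  row_a <- strsplit(write_mitab(doc_a)[2], "\t", fixed = TRUE)[[1]]
  expect_identical(row_a[37], "binding site:-2000--1")

  # molecule-set participant: set identity in the type column, candidates
  # in the alias column
  doc_i <- mif_use_case("i")
  row_i <- strsplit(write_mitab(doc_i)[2], "\t", fixed = TRUE)[[1]]
  expect_match(row_i[21], "MI:1305", fixed = TRUE)
  expect_match(row_i[5], "CALM1", fixed = TRUE)
  expect_match(row_i[5], "CALM3", fixed = TRUE)
})
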