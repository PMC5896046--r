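test_that("use-case fixtures carry the advertised constructs", {
  a <- mif_use_case("a")
  r <- a$entries[[1]]$interactions[[1]]$participants[[1]]$features[[1]]$ranges[[1]]
  expect_identical(r$begin$value, -2000L)
  expect_identical(r$end$value, -1L)

  f <- mif_use_case("f")
  vp <- f$entries[[1]]$experiments[[1]]$variable_parameters[[1]]
  expect_match(vp$description, "hours post-Sendai")
  expect_gte(length(vp$values), 3L)
  orders <- vapply(vp$values, function(v) v$order, integer(1))
  expect_identical(orders, sort(orders))
  refs <- unlist(lapply(f$entries[[1]]$interactions,
                        function(ia) unlist(ia$condition_sets)))
  expect_identical(anyDuplicated(refs), 0L)    # distinct values referenced

  h <- mif_use_case("h")
  abs_idx <- which(vapply(h$entries[[1]]$interactions, inherits, logical(1),
                          "mif_abstract_interaction"))
  eff <- h$entries[[1]]$interactions[[abs_idx]]$cooperative_effects[[1]]
  expect_identical(eff$kind, "allostery")
  expect_false(is.null(eff$outcome))
  expect_false(is.null(eff$allosteric_molecule_ref))
  expect_identical(eff$effector$kind, "molecule")
  expect_length(eff$affected_refs, 1L)

  i <- mif_use_case("i")
  p <- i$entries[[1]]$interactions[[1]]$participants[[1]]
  expect_identical(p$entity$kind, "candidate_set")
  expect_length(p$entity$set$candidates, 3L)
  labels <- vapply(p$entity$set$candidates, function(cand) {
    Filter(function(it) it$id == cand$interactor_ref,
           i$entries[[1]]$interactors)[[1]]$names$short_label
  }, character(1))
  expect_setequal(labels, c("CALM1", "CALM2", "CALM3"))
})

test_that("unknown use-case tokens are rejected", {
  expect_error(mif_use_case("z"), "unknown use case")
})

test_that("generation is deterministic: same spec and seed, identical bytes", {
  spec <- mif_generator_spec(seed = 42L)
  expect_identical(write_mif(mif_generate(spec)),
                   write_mif(mif_generate(spec)))
  expect_false(identical(write_mif(mif_generate(spec)),
                         write_mif(mif_generate(mif_generator_spec(43L)))))
})

test_that("generation leaves the caller's RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(mif_generate(mif_generator_spec(seed = 3L)))
  expect_identical(.Random.seed, before)
})

test_that("a no-flags spec yields a document with no 3.0-only constructs", {
  d <- mif_generate(mif_generator_spec(seed = 9L, flags = character()))
  res <- mif_downgrade(d)
  expect_length(res$report$items, 0L)
})

test_that("all-flags documents instantiate every flag and stay validator-clean", {
  d <- mif_generate(mif_generator_spec(seed = 12L))
  cats <- unique(vapply(psimif:::scan_30_constructs(d),
                        function(it) it$category, character(1)))
  expect_setequal(cats, psimif:::LOSS_CATEGORIES)
  for (s in 1:20) {
    d <- mif_generate(mif_generator_spec(seed = s))
    expect_identical(
      mif_n_findings(mif_validate(d, profile = "cv"), "error"), 0L,
      label = sprintf("seed %d", s))
  }
})

test_that("infeasible generator specs fail loudly", {
  spec <- mif_generator_spec(seed = 1L, n_interactors = c(0L, 0L),
                             n_interactions = c(1L, 1L),
                             flags = character())
  expect_error(mif_generate(spec), class = "psimif_spec")
  expect_error(mif_generator_spec(seed = 1L, flags = "warp_drive"),
               "unknown generator flag")
})

test_that("shipped fixture files match regenerated documents", {
  dir <- system.file("extdata", "fixtures", package = "psimif")
  expect_true(nzchar(dir))
  for (case in mif_use_cases()) {
    path <- file.path(dir, sprintf("case-%s.xml", case))
    expect_true(file.exists(path))
    shipped <- read_mif(path, strict = TRUE)$document
    expect_semantically_equal(shipped, mif_normalize(mif_use_case(case)))
    man <- jsonlite::fromJSON(file.path(dir,
                                        sprintf("case-%s.manifest.json",
                                                case)))
    expect_identical(sort(names(man)),
                     sort(names(attr(mif_use_case(case), "loss_manifest"))))
  }
})

test_that("generator output is closed under the full pipeline", {
  d <- mif_generate(mif_generator_spec(seed = 314L))
  for (form in c("compact", "extended")) {
    rr <- read_mif(write_mif(d, form = form), strict = TRUE)
    expect_semantically_equal(rr$document, mif_normalize(d))
  }
  expect_identical(mif_n_findings(mif_validate(d, "cv"), "error"), 0L)
  res <- mif_downgrade(d)
  expect_semantically_equal(mif_upgrade(res$document, promote = TRUE),
                            mif_normalize(d))
  expect_silent(suppressMessages(write_mitab(d)))
})
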