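# Shared builders for small documents used across test files.

tiny_binary_doc <- function() {
  ex <- mif_experiment(1L, mif_bibref(mif_xref(mif_dbref("pubmed", "100"))),
                       mif_cv("two hybrid", mi_accession = "MI:0018"))
  i1 <- mif_interactor(2L, mif_cv("protein", mi_accession = "MI:0326"),
                       names = mif_names("p_one"))
  i2 <- mif_interactor(3L, mif_cv("protein", mi_accession = "MI:0326"),
                       names = mif_names("p_two"))
  ia <- mif_interaction(
    4L, 1L,
    list(mif_participant(5L, mif_entity(interactor_ref = 2L),
                         experimental_roles = list(
                           mif_cv("bait", mi_accession = "MI:0496"))),
         mif_participant(6L, mif_entity(interactor_ref = 3L),
                         experimental_roles = list(
                           mif_cv("prey", mi_accession = "MI:0498")))),
    interaction_types = list(mif_cv("physical association",
                                    mi_accession = "MI:0915")))
  mif_document(mif_entry(experiments = list(ex),
                         interactors = list(i1, i2),
                         interactions = list(ia)))
}

# an n-participant evidence interaction appended to a fresh document
nary_doc <- function(counts, with_bait = TRUE) {
  nid_env <- new.env(); nid_env$n <- 0L
  nid <- function() { nid_env$n <- nid_env$n + 1L; nid_env$n }
  ex <- mif_experiment(nid(), mif_bibref(mif_xref(mif_dbref("pubmed", "7"))),
                       mif_cv("two hybrid", mi_accession = "MI:0018"))
  prot <- mif_cv("protein", mi_accession = "MI:0326")
  interactors <- lapply(seq_len(max(counts)), function(k) {
    mif_interactor(nid(), prot, names = mif_names(sprintf("prot_%d", k)))
  })
  interactions <- lapply(counts, function(n) {
    ps <- lapply(seq_len(n), function(j) {
      roles <- if (j == 1L && with_bait) {
        list(mif_cv("bait", mi_accession = "MI:0496"))
      } else {
        list(mif_cv("prey", mi_accession = "MI:0498"))
      }
      mif_participant(nid(),
                      mif_entity(interactor_ref = interactors[[j]]$id),
                      experimental_roles = roles)
    })
    mif_interaction(nid(), ex$id, ps)
  })
  mif_document(mif_entry(experiments = list(ex), interactors = interactors,
                         interactions = interactions))
}

expect_semantically_equal <- function(a, b) {
  eq <- mif_semantic_equal(a, b)
  if (!eq$equal) {
    msg <- paste(vapply(eq$diffs[seq_len(min(5, length(eq$diffs)))],
                        function(d) paste0(d$path, ": ", d$description),
                        character(1)),
                 collapse = "; ")
    fail(sprintf("documents differ: %s", msg))
  } else {
    succeed()
  }
  invisible(eq)
}

error_codes <- function(findings) {
  unique(vapply(Filter(function(f) f$severity == "error", findings),
                function(f) f$code, character(1)))
}

all_codes <- function(findings) {
  vapply(findings, function(f) f$code, character(1))
}
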