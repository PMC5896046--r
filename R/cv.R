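# Minimal embedded PSI-MI controlled-vocabulary store.
#
# The store maps MI accessions to a label and optional parent accessions.
# It is deliberately small: enough for accession-known checks and for the
# terms the package itself emits.  A full ontology can be merged in from an
# OBO file with mif_load_cv().

embedded_cv_terms <- function() {
  t <- function(acc, label, parents = character(0)) {
    list(accession = acc, label = label, parents = parents)
  }
  list(
    t("MI:0000", "molecular interaction"),
    t("MI:0001", "interaction detection method", "MI:0000"),
    t("MI:0004", "affinity chromatography technology", "MI:0001"),
    t("MI:0013", "biophysical", "MI:0001"),
    t("MI:0018", "two hybrid", "MI:0001"),
    t("MI:0019", "coimmunoprecipitation", "MI:0004"),
    t("MI:0077", "nuclear magnetic resonance", "MI:0013"),
    t("MI:0113", "western blot", "MI:0001"),
    t("MI:0114", "x-ray crystallography", "MI:0013"),
    t("MI:0116", "feature type", "MI:0000"),
    t("MI:0117", "binding site", "MI:0116"),
    t("MI:0118", "mutation", "MI:0116"),
    t("MI:0190", "interaction type", "MI:0000"),
    t("MI:0313", "interactor type", "MI:0000"),
    t("MI:0314", "complex", "MI:0313"),
    t("MI:0319", "deoxyribonucleic acid", "MI:0313"),
    t("MI:0320", "ribonucleic acid", "MI:0313"),
    t("MI:0326", "protein", "MI:0313"),
    t("MI:0328", "small molecule", "MI:0313"),
    t("MI:0333", "feature range status", "MI:0000"),
    t("MI:0335", "certain", "MI:0333"),
    t("MI:0339", "undetermined", "MI:0333"),
    t("MI:0356", "identity", "MI:0000"),
    t("MI:0363", "inferred by author", "MI:0001"),
    t("MI:0364", "inferred by curator", "MI:0001"),
    t("MI:0367", "green fluorescent protein tag", "MI:0116"),
    t("MI:0407", "direct interaction", "MI:0915"),
    t("MI:0421", "identification by antibody", "MI:0001"),
    t("MI:0442", "sufficient binding region", "MI:0116"),
    t("MI:0488", "psi-mi", "MI:0000"),
    t("MI:0495", "experimental role", "MI:0000"),
    t("MI:0496", "bait", "MI:0495"),
    t("MI:0498", "prey", "MI:0495"),
    t("MI:0499", "unspecified role", "MI:0495"),
    t("MI:0500", "biological role", "MI:0000"),
    t("MI:0501", "enzyme", "MI:0500"),
    t("MI:0502", "enzyme target", "MI:0500"),
    t("MI:0638", "prerequisite-ptm", "MI:0116"),
    t("MI:0904", "polysaccharide", "MI:0313"),
    t("MI:0914", "association", "MI:0190"),
    t("MI:0915", "physical association", "MI:0914"),
    t("MI:0925", "observed-ptm", "MI:0116"),
    t("MI:0943", "detection by mass spectrometry", "MI:0001"),
    t("MI:1304", "molecule set", "MI:0313"),
    t("MI:1305", "candidate set", "MI:1304")
  )
}

new_cv_store <- function(terms) {
  index <- new.env(parent = emptyenv())
  for (tm in terms) assign(tm$accession, tm, envir = index)
  structure(list(index = index), class = "mif_cv_store")
}

#' Embedded minimal CV store
#'
#' @return A `mif_cv_store` pre-loaded with the accessions the package
#'   relies on (interactor types, roles, range statuses, feature roles,
#'   inference methods, ...).
#' @export
#' @examples
#' store <- mif_cv_store()
#' mif_cv_known(store, "MI:0326")
mif_cv_store <- function() {
  new_cv_store(embedded_cv_terms())
}

#' Look up an accession in a CV store
#'
#' Lookups are total: an unknown accession returns `NULL` (known check:
#' `FALSE`), never an error.
#'
#' @param store A `mif_cv_store`.
#' @param accession Accession string, e.g. `"MI:0326"`.
#' @return `mif_cv_lookup()`: the term record (`accession`, `label`,
#'   `parents`) or `NULL`; `mif_cv_known()`: a boolean.
#' @export
mif_cv_lookup <- function(store, accession) {
  if (!inherits(store, "mif_cv_store")) mif_abort("`store` must be a <mif_cv_store>")
  if (!is.character(accession) || length(accession) != 1L) return(NULL)
  if (!exists(accession, envir = store$index, inherits = FALSE)) return(NULL)
  get(accession, envir = store$index, inherits = FALSE)
}

#' @rdname mif_cv_lookup
#' @export
mif_cv_known <- function(store, accession) {
  !is.null(mif_cv_lookup(store, accession))
}

#' @export
print.mif_cv_store <- function(x, ...) {
  cat(sprintf("<CV store: %d term(s)>\n", length(ls(x$index))))
  invisible(x)
}

#' Load a controlled vocabulary from an OBO stream
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping every term whose
#' id matches `MI:` + 4 digits, and merges them over the embedded minimal
#' store; on a label conflict the file wins.  A stanza without a valid id
#' is skipped, with a warning finding attached to the result as the
#' `"findings"` attribute.
#'
#' @param x Path to an OBO file, or the OBO text itself.
#' @return A `mif_cv_store`.
#' @export
mif_load_cv <- function(x) {
  lines <- if (is.character(x) && length(x) == 1L && !grepl("\n", x) &&
               file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
  }
  terms <- list()
  findings <- list()
  i <- 1L
  n <- length(lines)
  stanza_no <- 0L
  while (i <= n) {
    if (trimws(lines[i]) == "[Term]") {
      stanza_no <- stanza_no + 1L
      j <- i + 1L
      id <- NULL; name <- NULL; parents <- character(0)
      while (j <= n && !grepl("^\\[", trimws(lines[j]))) {
        ln <- trimws(lines[j])
        if (grepl("^id:", ln)) {
          id <- trimws(sub("^id:", "", ln))
        } else if (grepl("^name:", ln)) {
          name <- trimws(sub("^name:", "", ln))
        } else if (grepl("^is_a:", ln)) {
          pa <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
          if (grepl("^MI:[0-9]{4}$", pa)) parents <- c(parents, pa)
        }
        j <- j + 1L
      }
      if (!is.null(id) && grepl("^MI:[0-9]{4}$", id)) {
        terms[[length(terms) + 1L]] <-
          list(accession = id, label = name %||% id, parents = parents)
      } else {
        findings[[length(findings) + 1L]] <- new_finding(
          "OBO_STANZA_SKIPPED", "warning",
          sprintf("stanza[%d]", stanza_no),
          sprintf("skipped stanza with id '%s'", id %||% "<missing>"))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  merged <- embedded_cv_terms()
  by_acc <- stats::setNames(seq_along(merged),
                            vapply(merged, `[[`, character(1), "accession"))
  for (tm in terms) {
    k <- if (tm$accession %in% names(by_acc)) by_acc[[tm$accession]] else NA_integer_
    if (!is.na(k)) {
      merged[[k]] <- tm           # file wins on conflicts
    } else {
      merged[[length(merged) + 1L]] <- tm
      by_acc[[tm$accession]] <- length(merged)
    }
  }
  store <- new_cv_store(merged)
  attr(store, "findings") <- findings
  store
}
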