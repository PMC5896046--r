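# Semantic validation beyond the structural grammar: reference closure,
# content rules, and CV accession checks against a store.
#
# Severity policy: violations of rules the format states are errors;
# conventions it implies (zero coordinates, mixing evidence and abstract
# interactions in one list, duplicate order values) are warnings.

#' Closed list of validation finding codes
#'
#' @return Data frame with `code`, `severity` and `profile` columns — the
#'   published closed list of finding codes [mif_validate()] can emit.
#' @export
mif_finding_codes <- function() {
  data.frame(
    code = c("ID_DUPLICATE", "DANGLING_REF", "NO_PARTICIPANTS",
             "EVIDENCE_NO_EXPERIMENT", "ABSTRACT_HAS_EXPERIMENT",
             "EMPTY_RANGES",
             "RESSEQ_EMPTY", "RESSEQ_BAD_SEQUENCE", "RANGE_INVERTED",
             "STOICH_RANGE_INVERTED", "STOICH_NEGATIVE",
             "FEATURE_ROLE_NO_ACCESSION", "ORDER_NEGATIVE",
             "POSITION_ZERO", "NEG_POS_ON_PROTEIN", "ORDER_DUPLICATE",
             "MIXED_INTERACTION_KINDS",
             "CV_BAD_ACCESSION", "CV_UNKNOWN"),
    severity = c("error", "error", "error", "error", "error", "error",
                 "error", "error", "error", "error", "error", "error",
                 "error",
                 "warning", "warning", "warning", "warning",
                 "error", "warning"),
    profile = c(rep("structural", 6), rep("semantic", 11), rep("cv", 2)),
    stringsAsFactors = FALSE
  )
}

IUPAC_SEQ_RE <- "^[A-Za-z]+$"

#' Validate a document
#'
#' Emits an ordered, deterministic list of findings.  The `structural`
#' profile checks id uniqueness, reference closure and required content;
#' `semantic` (the default) adds the content rules (resulting-sequence
#' emptiness, inverted ranges and stoichiometries, feature-role
#' accessions, coordinate conventions, order duplicates, mixed interaction
#' kinds); `cv` additionally checks every CV accession's format and its
#' presence in the store.  Rules never raise: all outcomes are findings.
#'
#' @param doc A [mif_document()].
#' @param profile One of `"structural"`, `"semantic"`, `"cv"`; each level
#'   includes the previous ones.
#' @param cv_store A `mif_cv_store` (default [mif_cv_store()]).
#' @param suppress Character vector of finding codes to drop.
#' @return List of `mif_finding` records (class `mif_findings`), each with
#'   `code`, `severity`, `path`, `message`.
#' @export
mif_validate <- function(doc, profile = c("semantic", "structural", "cv"),
                         cv_store = NULL, suppress = character()) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  profile <- match.arg(profile)
  levels_on <- switch(profile,
                      structural = "structural",
                      semantic = c("structural", "semantic"),
                      cv = c("structural", "semantic", "cv"))
  out <- new.env(parent = emptyenv())
  out$items <- list()
  add <- function(code, path, message) {
    codes <- mif_finding_codes()
    sev <- codes$severity[match(code, codes$code)]
    out$items[[length(out$items) + 1L]] <-
      new_finding(code, sev, path, message)
  }

  for (ei in seq_along(doc$entries)) {
    entry <- doc$entries[[ei]]
    epath <- sprintf("entries[%d]", ei)

    # -- structural ----------------------------------------------------------
    ids <- entry_defined_ids(entry)
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) {
      add("ID_DUPLICATE", epath, sprintf("id %d defined more than once", d))
    }
    for (r in entry_references(entry)) {
      if (!r$id %in% ids) {
        add("DANGLING_REF", sprintf("%s/%s", epath, r$path),
            sprintf("reference to undefined id %d", r$id))
      }
    }

    kinds <- vapply(entry$interactions, function(ia) {
      if (inherits(ia, "mif_interaction")) "evidence" else "abstract"
    }, character(1))

    for (ii in seq_along(entry$interactions)) {
      ia <- entry$interactions[[ii]]
      ipath <- sprintf("%s/interactions[%d]", epath, ii)
      if (inherits(ia, "mif_interaction")) {
        if (length(ia$participants) == 0L) {
          add("NO_PARTICIPANTS", ipath, "evidence interaction has no participants")
        }
        if (length(ia$experiment_refs) == 0L) {
          add("EVIDENCE_NO_EXPERIMENT", ipath,
              "evidence interaction references no experiment")
        }
      } else if (length(ia$experiment_refs) > 0L) {
        add("ABSTRACT_HAS_EXPERIMENT", ipath,
            "abstract interactions are evidence-free and must not reference experiments")
      }
      walk_features_structural(ia, ipath, add)
    }

    # -- semantic ------------------------------------------------------------
    if ("semantic" %in% levels_on) {
      interactor_type <- function(ref) {
        for (it in entry$interactors) {
          if (it$id == ref) return(it$interactor_type)
        }
        NULL
      }
      for (ii in seq_along(entry$interactions)) {
        ia <- entry$interactions[[ii]]
        ipath <- sprintf("%s/interactions[%d]", epath, ii)
        for (pi in seq_along(ia$participants)) {
          p <- ia$participants[[pi]]
          ppath <- sprintf("%s/participants[%d]", ipath, pi)
          check_stoichiometry(p$stoichiometry, ppath, add)
          it_type <- if (p$entity$kind == "interactor_ref") {
            interactor_type(p$entity$ref)
          } else {
            NULL
          }
          flist <- list(list(features = p$features, path = ppath))
          if (p$entity$kind == "candidate_set") {
            for (ci in seq_along(p$entity$set$candidates)) {
              flist[[length(flist) + 1L]] <- list(
                features = p$entity$set$candidates[[ci]]$features,
                path = sprintf("%s/candidates[%d]", ppath, ci))
            }
          }
          for (fl in flist) {
            for (fi in seq_along(fl$features)) {
              check_feature_semantic(fl$features[[fi]],
                                     sprintf("%s/features[%d]", fl$path, fi),
                                     it_type, add)
            }
          }
        }
      }
      for (xi in seq_along(entry$experiments)) {
        ex <- entry$experiments[[xi]]
        for (vi in seq_along(ex$variable_parameters)) {
          vp <- ex$variable_parameters[[vi]]
          vpath <- sprintf("%s/experiments[%d]/variableParameter[%d]",
                           epath, xi, vi)
          orders <- unlist(lapply(vp$values, function(v) v$order))
          if (length(orders) && anyDuplicated(orders)) {
            add("ORDER_DUPLICATE", vpath,
                "duplicate order values within one variableValueList")
          }
          for (v in vp$values) {
            if (!is.null(v$order) && v$order < 0L) {
              add("ORDER_NEGATIVE", vpath,
                  sprintf("order %d of value id %d is negative", v$order, v$id))
            }
          }
        }
      }
      if (all(c("evidence", "abstract") %in% kinds)) {
        add("MIXED_INTERACTION_KINDS", epath,
            "entry mixes evidence and abstract interactions in one interaction list")
      }
    }

    # -- cv ------------------------------------------------------------------
    if ("cv" %in% levels_on) {
      store <- cv_store %||% mif_cv_store()
      walk_cv_terms(entry, epath, function(cv, path) {
        acc <- cv$mi_accession
        if (is.null(acc)) return(invisible(NULL))
        if (!is_mi_accession(acc)) {
          add("CV_BAD_ACCESSION", path,
              sprintf("accession '%s' does not match MI: + 4 digits", acc))
        } else if (!mif_cv_known(store, acc)) {
          add("CV_UNKNOWN", path,
              sprintf("accession %s not found in the CV store", acc))
        }
        invisible(NULL)
      })
    }
  }
  items <- Filter(function(f) !f$code %in% suppress, out$items)
  structure(items, class = "mif_findings")
}

walk_features_structural <- function(ia, ipath, add) {
  for (pi in seq_along(ia$participants)) {
    p <- ia$participants[[pi]]
    ppath <- sprintf("%s/participants[%d]", ipath, pi)
    feats <- list(list(features = p$features, path = ppath))
    if (p$entity$kind == "candidate_set") {
      for (ci in seq_along(p$entity$set$candidates)) {
        feats[[length(feats) + 1L]] <- list(
          features = p$entity$set$candidates[[ci]]$features,
          path = sprintf("%s/candidates[%d]", ppath, ci))
      }
    }
    for (fl in feats) {
      for (fi in seq_along(fl$features)) {
        if (length(fl$features[[fi]]$ranges) == 0L) {
          add("EMPTY_RANGES", sprintf("%s/features[%d]", fl$path, fi),
              "feature has no ranges")
        }
      }
    }
  }
}

is_certain_status <- function(cv) {
  if (is.null(cv)) return(FALSE)
  identical(cv$mi_accession, "MI:0335") ||
    identical(tolower(cv$short_label %||% ""), "certain")
}

check_stoichiometry <- function(st, path, add) {
  sp <- paste0(path, "/stoichiometry")
  if (st$kind == "range") {
    if (isTRUE(st$min_value > st$max_value)) {
      add("STOICH_RANGE_INVERTED", sp,
          sprintf("stoichiometry range %s..%s is inverted",
                  format(st$min_value), format(st$max_value)))
    }
    if (isTRUE(st$min_value < 0) || isTRUE(st$max_value < 0)) {
      add("STOICH_NEGATIVE", sp, "stoichiometry values must be >= 0")
    }
  } else if (st$kind == "mean" && isTRUE(st$value < 0)) {
    add("STOICH_NEGATIVE", sp, "stoichiometry values must be >= 0")
  }
}

position_values <- function(pos) {
  switch(pos$kind,
         exact = pos$value,
         interval = c(pos$start, pos$end),
         integer(0))
}

check_feature_semantic <- function(f, fpath, interactor_type, add) {
  if (!is.null(f$feature_role) && is.null(f$feature_role$mi_accession)) {
    add("FEATURE_ROLE_NO_ACCESSION", paste0(fpath, "/featureRole"),
        "a feature role must carry an MI accession")
  }
  on_protein <- !is.null(interactor_type) &&
    (identical(interactor_type$mi_accession, "MI:0326") ||
       identical(tolower(interactor_type$short_label %||% ""), "protein"))
  for (ri in seq_along(f$ranges)) {
    r <- f$ranges[[ri]]
    rpath <- sprintf("%s/ranges[%d]", fpath, ri)
    vals <- c(position_values(r$begin), position_values(r$end))
    if (any(vals == 0L)) {
      add("POSITION_ZERO", rpath,
          "coordinate 0 does not exist in 1-based biological coordinates")
    }
    if (on_protein && any(vals < 0L)) {
      add("NEG_POS_ON_PROTEIN", rpath,
          "negative coordinates describe genomic regions, not protein sequences")
    }
    if (r$begin$kind == "exact" && r$end$kind == "exact" &&
        is_certain_status(r$begin_status) && is_certain_status(r$end_status) &&
        r$begin$value > r$end$value) {
      add("RANGE_INVERTED", rpath,
          sprintf("certain range %d..%d is inverted",
                  r$begin$value, r$end$value))
    }
    rs <- r$resulting_sequence
    if (!is.null(rs)) {
      has_seqs <- !is.null(rs$original) && !is.null(rs$new)
      if (!has_seqs && is.null(rs$xref)) {
        add("RESSEQ_EMPTY", paste0(rpath, "/resultingSequence"),
            "a resulting sequence needs both sequences or an xref")
      }
      for (s in c(rs$original, rs$new)) {
        if (!is.null(s) && !grepl(IUPAC_SEQ_RE, s)) {
          add("RESSEQ_BAD_SEQUENCE", paste0(rpath, "/resultingSequence"),
              sprintf("'%s' is not an IUPAC letter sequence", s))
        }
      }
    }
  }
}

# call fn(cv, path) on every CV term reachable from x
walk_cv_terms <- function(x, path, fn) {
  if (!is.list(x)) return(invisible(NULL))
  if (inherits(x, "mif_cv")) {
    fn(x, path)
    if (!is.null(x$xref)) walk_cv_terms(x$xref, paste0(path, "/xref"), fn)
    return(invisible(NULL))
  }
  nm <- names(x)
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (is.null(v) || !is.list(v)) next
    tag <- if (is.null(nm) || nm[i] == "") sprintf("[%d]", i)
           else paste0("/", nm[i])
    walk_cv_terms(v, paste0(path, tag), fn)
  }
  invisible(NULL)
}

#' @export
print.mif_findings <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<no findings>\n")
    return(invisible(x))
  }
  cat(sprintf("<%d finding(s)>\n", length(x)))
  for (f in x) {
    cat(sprintf("  [%s] %s at %s: %s\n", f$severity, f$code, f$path,
                f$message))
  }
  invisible(x)
}

#' Serialize findings
#'
#' @param findings A `mif_findings` list.
#' @return `mif_findings_json()`: one JSON object per line (code, severity,
#'   path, message); `mif_findings_text()`: human-readable lines.
#' @export
mif_findings_json <- function(findings) {
  vapply(findings, function(f) {
    as.character(jsonlite::toJSON(
      list(code = f$code, severity = f$severity, path = f$path,
           message = f$message),
      auto_unbox = TRUE))
  }, character(1))
}

#' @rdname mif_findings_json
#' @export
mif_findings_text <- function(findings) {
  vapply(findings, function(f) {
    sprintf("[%s] %s at %s: %s", f$severity, f$code, f$path, f$message)
  }, character(1))
}

#' Count findings of a given severity
#' @param findings A `mif_findings` list.
#' @param severity Severity class to count.
#' @return Integer count.
#' @export
mif_n_findings <- function(findings, severity = "error") {
  sum(vapply(findings, function(f) f$severity == severity, logical(1)))
}
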