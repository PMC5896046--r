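# Id namespace and reference-graph helpers.
#
# Every entry owns a single integer id namespace shared by availabilities,
# experiments, variable values, interactors, interactions, participants,
# candidates and features.  Definitions are collected in document order;
# references must form a closed graph over the defined ids.

ID_FIELDS_SCALAR <- c("id", "ref", "experiment_ref", "interactor_ref",
                      "allosteric_molecule_ref")
ID_FIELDS_VECTOR <- c("experiment_refs", "affected_refs")
ID_FIELDS_SETLIST <- c("condition_sets", "binding_features")

# ids defined by an entry, in document order (first-encounter)
entry_defined_ids <- function(entry) {
  out <- integer(0)
  add <- function(x) out <<- c(out, as.integer(x))
  for (av in entry$availabilities) add(av$id)
  for (ex in entry$experiments) {
    add(ex$id)
    for (vp in ex$variable_parameters) {
      for (vv in vp$values) add(vv$id)
    }
  }
  for (it in entry$interactors) add(it$id)
  walk_feature <- function(f) add(f$id)
  walk_participant <- function(p) {
    add(p$id)
    if (p$entity$kind == "candidate_set") {
      for (cand in p$entity$set$candidates) {
        add(cand$id)
        for (f in cand$features) walk_feature(f)
      }
    }
    for (f in p$features) walk_feature(f)
  }
  for (ia in entry$interactions) {
    add(ia$id)
    for (p in ia$participants) walk_participant(p)
  }
  out
}

# all id references made by an entry, with the path of each
entry_references <- function(entry) {
  refs <- list()
  add <- function(id, path) {
    refs[[length(refs) + 1L]] <<- list(id = as.integer(id), path = path)
  }
  walk_params <- function(params, path) {
    for (k in seq_along(params)) {
      er <- params[[k]]$experiment_ref
      if (!is.null(er)) add(er, sprintf("%s/parameters[%d]", path, k))
    }
  }
  walk_participant <- function(p, path) {
    if (p$entity$kind %in% c("interactor_ref", "interaction_ref")) {
      add(p$entity$ref, paste0(path, "/entity"))
    } else {
      for (ci in seq_along(p$entity$set$candidates)) {
        cand <- p$entity$set$candidates[[ci]]
        add(cand$interactor_ref,
            sprintf("%s/candidates[%d]", path, ci))
        for (fi in seq_along(cand$features)) {
          walk_params(cand$features[[fi]]$parameters,
                      sprintf("%s/candidates[%d]/features[%d]", path, ci, fi))
        }
      }
    }
    for (fi in seq_along(p$features)) {
      walk_params(p$features[[fi]]$parameters,
                  sprintf("%s/features[%d]", path, fi))
    }
    walk_params(p$parameters, path)
  }
  for (ii in seq_along(entry$interactions)) {
    ia <- entry$interactions[[ii]]
    path <- sprintf("interactions[%d]", ii)
    for (er in ia$experiment_refs) add(er, paste0(path, "/experimentRef"))
    for (pi in seq_along(ia$participants)) {
      walk_participant(ia$participants[[pi]],
                       sprintf("%s/participants[%d]", path, pi))
    }
    if (inherits(ia, "mif_interaction")) {
      for (si in seq_along(ia$condition_sets)) {
        for (vv in ia$condition_sets[[si]]) {
          add(vv, sprintf("%s/variableValueRefList[%d]", path, si))
        }
      }
      for (gi in seq_along(ia$inferred_interactions)) {
        for (item in ia$inferred_interactions[[gi]]) {
          add(item$ref, sprintf("%s/inferredInteraction[%d]", path, gi))
        }
      }
      walk_params(ia$parameters, path)
    } else {
      for (bi in seq_along(ia$binding_features)) {
        for (fr in ia$binding_features[[bi]]) {
          add(fr, sprintf("%s/bindingFeatures[%d]", path, bi))
        }
      }
      for (ei in seq_along(ia$cooperative_effects)) {
        eff <- ia$cooperative_effects[[ei]]
        epath <- sprintf("%s/cooperativeEffect[%d]", path, ei)
        for (ar in eff$affected_refs) {
          add(ar, paste0(epath, "/affectedInteractionRef"))
        }
        if (eff$kind == "allostery") {
          add(eff$allosteric_molecule_ref,
              paste0(epath, "/allostericMoleculeRef"))
          add(eff$effector$ref, paste0(epath, "/effector"))
        }
      }
    }
  }
  refs
}

# dangling references of a document: list of (entry, id, path)
document_dangling_refs <- function(doc) {
  out <- list()
  for (ei in seq_along(doc$entries)) {
    entry <- doc$entries[[ei]]
    defined <- entry_defined_ids(entry)
    for (r in entry_references(entry)) {
      if (!r$id %in% defined) {
        out[[length(out) + 1L]] <- list(entry = ei, id = r$id,
                                        path = sprintf("entries[%d]/%s",
                                                       ei, r$path))
      }
    }
  }
  out
}

assert_resolved <- function(doc, what = "document") {
  dangling <- document_dangling_refs(doc)
  if (length(dangling) > 0L) {
    d <- dangling[[1L]]
    mif_abort(
      sprintf("%s has %d unresolved reference(s); first: id %d at %s",
              what, length(dangling), d$id, d$path),
      class = "psimif_unresolved", dangling = dangling
    )
  }
  invisible(doc)
}

# ---- canonical ordering -----------------------------------------------------

# sort key for a CV term / candidate that must not involve ids
cand_sort_key <- function(cand, interactor_index) {
  it <- interactor_index[[as.character(cand$interactor_ref)]]
  if (is.null(it)) return("~unresolved")
  paste(it$names$short_label %||% "", it$names$full_name %||% "",
        it$interactor_type$short_label %||% "", sep = "\r")
}

sort_attributes <- function(attrs) {
  if (length(attrs) <= 1L) return(attrs)
  keys <- vapply(attrs, function(a) {
    paste(a$name, a$value %||% "", a$name_ac %||% "", sep = "\r")
  }, character(1))
  attrs[order(keys, method = "radix")]
}

sort_secondary <- function(refs) {
  if (length(refs) <= 1L) return(refs)
  keys <- vapply(refs, function(r) {
    paste(r$db, r$id, r$ref_type %||% "", sep = "\r")
  }, character(1))
  refs[order(keys, method = "radix")]
}

cv_key <- function(cv) {
  if (is.null(cv)) return("")
  paste(cv$short_label %||% "", cv$mi_accession %||% "", sep = "\r")
}

interactor_key <- function(it) {
  paste(it$names$short_label %||% "", it$names$full_name %||% "",
        cv_key(it$interactor_type),
        if (is.null(it$organism)) "" else it$organism$ncbi_tax_id,
        it$sequence %||% "", sep = "\r")
}

experiment_key <- function(ex) {
  bib <- if (!is.null(ex$bibref$xref)) {
    paste(ex$bibref$xref$primary$db, ex$bibref$xref$primary$id)
  } else {
    ""
  }
  paste(ex$names$short_label %||% "", bib,
        cv_key(ex$interaction_detection_method), sep = "\r")
}

# recursively apply canonical ordering to unordered lists
canonical_sort <- function(x, interactor_index) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  for (i in seq_along(x)) {
    n <- if (is.null(nm)) "" else nm[i]
    v <- x[[i]]
    if (is.null(v)) next
    if (identical(n, "attributes")) {
      x[[i]] <- sort_attributes(v)
    } else if (identical(n, "experiments") && inherits(x, "mif_entry")) {
      # definition-list order is a serialization artifact (compact vs
      # extended first-use order), not semantics
      keys <- vapply(v, experiment_key, character(1))
      x[[i]] <- lapply(v[order(keys, method = "radix")],
                       canonical_sort, interactor_index)
    } else if (identical(n, "interactors") && inherits(x, "mif_entry")) {
      keys <- vapply(v, interactor_key, character(1))
      x[[i]] <- lapply(v[order(keys, method = "radix")],
                       canonical_sort, interactor_index)
    } else if (identical(n, "secondary")) {
      x[[i]] <- sort_secondary(v)
    } else if (identical(n, "candidates")) {
      keys <- vapply(v, cand_sort_key, character(1), interactor_index)
      v <- v[order(keys, method = "radix")]
      x[[i]] <- lapply(v, canonical_sort, interactor_index)
    } else if (is.list(v)) {
      x[[i]] <- canonical_sort(v, interactor_index)
    }
  }
  x
}

# recursively rewrite id fields through `fmap`
map_ids <- function(x, fmap) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  for (i in seq_along(x)) {
    n <- if (is.null(nm)) "" else nm[i]
    v <- x[[i]]
    if (is.null(v)) next
    if (n %in% ID_FIELDS_SCALAR && is.numeric(v)) {
      x[[i]] <- fmap(v)
    } else if (n %in% ID_FIELDS_VECTOR) {
      x[[i]] <- if (length(v)) vapply(as.list(v), fmap, integer(1)) else v
    } else if (n %in% ID_FIELDS_SETLIST) {
      x[[i]] <- lapply(v, function(s) {
        if (length(s)) vapply(as.list(s), fmap, integer(1)) else s
      })
    } else if (is.list(v)) {
      x[[i]] <- map_ids(v, fmap)
    }
  }
  x
}

#' Normalize a document
#'
#' Renumbers all ids densely from 1 in document order (the reference graph
#' is preserved), applies canonical ordering to the lists the schema treats
#' as unordered (attributes, secondary cross-references, interactor
#' candidates) and never drops content.  `mif_normalize()` is idempotent:
#' applying it twice yields a byte-identical serialization.
#'
#' @param doc A [mif_document()].
#' @return The normalized document.
#' @export
mif_normalize <- function(doc) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  assert_resolved(doc)
  next_id <- 0L
  doc$entries <- lapply(doc$entries, function(entry) {
    interactor_index <- list()
    for (it in entry$interactors) {
      interactor_index[[as.character(it$id)]] <- it
    }
    entry <- canonical_sort(entry, interactor_index)
    class(entry) <- "mif_entry"
    defined <- unique(entry_defined_ids(entry))
    map <- new.env(parent = emptyenv())
    for (old in defined) {
      next_id <<- next_id + 1L
      assign(as.character(old), next_id, envir = map)
    }
    fmap <- function(v) {
      key <- as.character(as.integer(v))
      if (!exists(key, envir = map, inherits = FALSE)) {
        mif_abort(sprintf("unresolved id %s during normalization", key),
                  class = "psimif_unresolved")
      }
      get(key, envir = map, inherits = FALSE)
    }
    entry <- map_ids(entry, fmap)
    class(entry) <- "mif_entry"
    entry
  })
  doc
}

# ---- semantic equality ------------------------------------------------------

deep_compare <- function(a, b, path, diffs) {
  if (is.null(a) && is.null(b)) return(invisible(NULL))
  if (is.null(a) || is.null(b)) {
    diffs$add(path, sprintf("present only in %s",
                            if (is.null(a)) "second" else "first"))
    return(invisible(NULL))
  }
  ca <- class(a); cb <- class(b)
  if (!identical(ca, cb)) {
    diffs$add(path, sprintf("class differs (%s vs %s)", ca[1], cb[1]))
    return(invisible(NULL))
  }
  if (!is.list(a)) {
    eq <- if (is.numeric(a) && is.numeric(b) && length(a) == length(b)) {
      isTRUE(all.equal(as.numeric(a), as.numeric(b), tolerance = 1e-9))
    } else {
      identical(a, b)
    }
    if (!eq) {
      diffs$add(path, sprintf("value differs (%s vs %s)",
                              paste(format(a), collapse = ","),
                              paste(format(b), collapse = ",")))
    }
    return(invisible(NULL))
  }
  nm_a <- names(a); nm_b <- names(b)
  if (is.null(nm_a) != is.null(nm_b)) {
    diffs$add(path, "list naming differs")
    return(invisible(NULL))
  }
  if (is.null(nm_a)) {
    if (length(a) != length(b)) {
      diffs$add(path, sprintf("length differs (%d vs %d)",
                              length(a), length(b)))
      return(invisible(NULL))
    }
    for (i in seq_along(a)) {
      deep_compare(a[[i]], b[[i]], sprintf("%s[%d]", path, i), diffs)
    }
    return(invisible(NULL))
  }
  fields <- union(nm_a, nm_b)
  fields <- fields[!grepl("_lexical$", fields)]  # lexical mirrors are cosmetic
  for (f in fields) {
    deep_compare(a[[f]], b[[f]], paste0(path, "/", f), diffs)
  }
  invisible(NULL)
}

#' Semantic document equality
#'
#' Compares two documents up to the semantics of the interchange format:
#' id values are ignored (only the reference graph matters), lists the
#' schema treats as unordered (attributes, secondary cross-references,
#' interactor candidates) are compared order-insensitively, and retained
#' lexical forms of decimals are ignored when the numeric values agree.
#' Both documents must be fully reference-resolved; a dangling reference
#' raises a classed error (`psimif_unresolved`) naming the id.
#'
#' @param a,b [mif_document()] objects.
#' @return An object of class `mif_equivalence`: a list with `equal`
#'   (boolean) and `diffs` (list of `path` + `description` records).
#' @export
#' @examples
#' d <- mif_document(mif_entry())
#' mif_semantic_equal(d, d)$equal
mif_semantic_equal <- function(a, b) {
  assert_resolved(a, "first document")
  assert_resolved(b, "second document")
  na <- mif_normalize(a)
  nb <- mif_normalize(b)
  store <- new.env(parent = emptyenv())
  store$items <- list()
  diffs <- list(add = function(path, description) {
    store$items[[length(store$items) + 1L]] <-
      list(path = path, description = description)
  })
  deep_compare(na, nb, "document", diffs)
  structure(list(equal = length(store$items) == 0L, diffs = store$items),
            class = "mif_equivalence")
}

#' @export
print.mif_equivalence <- function(x, ...) {
  if (x$equal) {
    cat("<documents semantically equal>\n")
  } else {
    cat(sprintf("<documents differ: %d difference(s)>\n", length(x$diffs)))
    for (d in x$diffs[seq_len(min(10L, length(x$diffs)))]) {
      cat(sprintf("  %s: %s\n", d$path, d$description))
    }
  }
  invisible(x)
}
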