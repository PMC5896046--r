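# MITAB 2.7 export: 42 tab-separated columns, one row per binary pair,
# n-ary evidence interactions expanded with the spoke model (hub = bait,
# else the first participant).  Abstract interactions carry no experimental
# evidence to tabulate and are skipped with a notice.

MITAB27_COLUMNS <- c(
  "ID(s) interactor A", "ID(s) interactor B",
  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
  "Alias(es) interactor A", "Alias(es) interactor B",
  "Interaction detection method(s)", "Publication 1st author(s)",
  "Publication Identifier(s)", "Taxid interactor A", "Taxid interactor B",
  "Interaction type(s)", "Source database(s)",
  "Interaction identifier(s)", "Confidence value(s)", "Expansion method(s)",
  "Biological role(s) interactor A", "Biological role(s) interactor B",
  "Experimental role(s) interactor A", "Experimental role(s) interactor B",
  "Type(s) interactor A", "Type(s) interactor B",
  "Xref(s) interactor A", "Xref(s) interactor B", "Interaction Xref(s)",
  "Annotation(s) interactor A", "Annotation(s) interactor B",
  "Interaction annotation(s)", "Host organism(s)",
  "Interaction parameter(s)", "Creation date", "Update date",
  "Checksum(s) interactor A", "Checksum(s) interactor B",
  "Interaction Checksum(s)", "Negative",
  "Feature(s) interactor A", "Feature(s) interactor B",
  "Stoichiometry(s) interactor A", "Stoichiometry(s) interactor B",
  "Identification method participant A", "Identification method participant B"
)

is_bait <- function(p) {
  for (r in p$experimental_roles) {
    if (identical(r$mi_accession, "MI:0496") ||
        identical(tolower(r$short_label %||% ""), "bait")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Expand an evidence interaction into binary pairs
#'
#' Two participants give one pair (`expansion = "none"`); n > 2 give n - 1
#' spoke pairs hubbed on the bait participant (else the first participant
#' in document order); a single intra-molecular participant gives one
#' self-pair.
#'
#' @param interaction A [mif_interaction()].
#' @return List of `mif_binary_pair` objects with fields `a`, `b`,
#'   `expansion`, `source_interaction_id`.
#' @export
mif_expand_binary <- function(interaction) {
  if (!inherits(interaction, "mif_interaction")) {
    mif_abort("`interaction` must be an evidence <mif_interaction>")
  }
  ps <- interaction$participants
  n <- length(ps)
  if (n == 0L) {
    mif_abort("cannot expand an interaction with zero participants",
              class = "psimif_expand")
  }
  pair <- function(a, b, expansion) {
    structure(list(a = a, b = b, expansion = expansion,
                   source_interaction_id = interaction$id),
              class = "mif_binary_pair")
  }
  if (n == 1L) {
    return(list(pair(ps[[1L]], ps[[1L]], "none")))
  }
  if (n == 2L) {
    return(list(pair(ps[[1L]], ps[[2L]], "none")))
  }
  hub_idx <- 1L
  for (i in seq_len(n)) {
    if (is_bait(ps[[i]])) {
      hub_idx <- i
      break
    }
  }
  lapply(setdiff(seq_len(n), hub_idx), function(i) {
    pair(ps[[hub_idx]], ps[[i]], "spoke")
  })
}

# sanitize a free-text cell fragment: no tabs, newlines or pipes may leak
mt_clean <- function(x) {
  x <- gsub("[\t\n\r|]", " ", x)
  gsub('"', "'", x)
}

mt_join <- function(values) {
  values <- values[nzchar(values)]
  if (length(values) == 0L) return("-")
  paste(values, collapse = "|")
}

mt_cv <- function(cv) {
  if (is.null(cv)) return(character(0))
  label <- mt_clean(cv$short_label %||% cv$full_name %||% "unknown")
  if (!is.null(cv$mi_accession)) {
    sprintf('psi-mi:"%s"(%s)', cv$mi_accession, label)
  } else {
    sprintf("psi-mi:%s", label)
  }
}

mt_xref_primary <- function(xref, fallback_label) {
  if (!is.null(xref)) {
    return(sprintf("%s:%s", mt_clean(xref$primary$db),
                   mt_clean(xref$primary$id)))
  }
  sprintf("psimif:%s", mt_clean(fallback_label))
}

mt_position <- function(pos) {
  switch(pos$kind,
         exact = as.character(pos$value),
         interval = sprintf("%d..%d", pos$start, pos$end),
         "?")
}

mt_features <- function(p) {
  feats <- p$features
  if (p$entity$kind == "candidate_set") {
    for (cand in p$entity$set$candidates) feats <- c(feats, cand$features)
  }
  vapply(feats, function(f) {
    tp <- mt_clean(f$feature_type$short_label %||% "feature")
    r <- f$ranges[[1L]]
    sprintf("%s:%s-%s", tp, mt_position(r$begin), mt_position(r$end))
  }, character(1))
}

mt_stoich <- function(p) {
  st <- p$stoichiometry
  switch(st$kind,
         mean = format(st$value, scientific = FALSE, trim = TRUE),
         range = sprintf("%s-%s",
                         format(st$min_value, scientific = FALSE, trim = TRUE),
                         format(st$max_value, scientific = FALSE, trim = TRUE)),
         "-")
}

mt_taxid <- function(org) {
  if (is.null(org)) return("-")
  label <- org$names$short_label %||% NULL
  if (is.null(label)) {
    sprintf("taxid:%d", org$ncbi_tax_id)
  } else {
    sprintf("taxid:%d(%s)", org$ncbi_tax_id, mt_clean(label))
  }
}

#' Export a document to MITAB 2.7
#'
#' Writes 42 tab-separated columns per binary pair; multi-valued cells are
#' pipe-separated, empty cells are `-`, free text is escaped so no tab,
#' newline or pipe characters leak.  Rows appear in document order, then
#' hub-spoke order.  Abstract interactions are skipped (they have no
#' experimental evidence); each skip emits a notice via `message()`.
#'
#' @param doc A [mif_document()].
#' @param path Optional output path for the TSV.
#' @param header Emit the `#`-prefixed column-header comment line
#'   (default TRUE).
#' @return Character vector of output lines (invisibly when written to
#'   `path`).
#' @export
write_mitab <- function(doc, path = NULL, header = TRUE) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  lines <- character(0)
  if (header) {
    lines <- paste0("#", paste(MITAB27_COLUMNS, collapse = "\t"))
  }
  for (ei in seq_along(doc$entries)) {
    entry <- doc$entries[[ei]]
    exp_index <- list()
    for (ex in entry$experiments) exp_index[[as.character(ex$id)]] <- ex
    int_index <- list()
    for (it in entry$interactors) int_index[[as.character(it$id)]] <- it
    source_db <- if (!is.null(entry$source)) {
      mt_clean(entry$source$names$short_label %||% "unknown")
    } else {
      "unknown"
    }
    for (ia in entry$interactions) {
      if (inherits(ia, "mif_abstract_interaction")) {
        message(sprintf(
          "mitab: skipping abstract interaction %d (no experimental evidence)",
          ia$id))
        next
      }
      if (length(ia$participants) == 0L) next
      experiments <- Filter(Negate(is.null),
                            lapply(ia$experiment_refs, function(r) {
                              exp_index[[as.character(r)]]
                            }))
      for (bp in mif_expand_binary(ia)) {
        lines <- c(lines,
                   mitab_row(bp, ia, experiments, int_index, source_db))
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

participant_interactor <- function(p, int_index) {
  if (p$entity$kind == "interactor_ref") {
    int_index[[as.character(p$entity$ref)]]
  } else {
    NULL
  }
}

participant_label <- function(p, it) {
  p$names$short_label %||% it$names$short_label %||%
    sprintf("participant-%d", p$id)
}

mitab_row <- function(bp, ia, experiments, int_index, source_db) {
  side <- function(p) {
    it <- participant_interactor(p, int_index)
    label <- participant_label(p, it)
    aliases <- if (p$entity$kind == "candidate_set") {
      # molecule set: candidates surface in the alias column
      vapply(p$entity$set$candidates, function(cand) {
        cit <- int_index[[as.character(cand$interactor_ref)]]
        sprintf("psimif:%s(candidate)",
                mt_clean(cit$names$short_label %||%
                           sprintf("candidate-%d", cand$id)))
      }, character(1))
    } else if (!is.null(it) && !is.null(it$names$full_name)) {
      sprintf("psimif:%s(full name)", mt_clean(it$names$full_name))
    } else {
      character(0)
    }
    list(
      id = mt_xref_primary(it$xref %||% NULL, label),
      alt = if (!is.null(it) && !is.null(it$names$short_label)) {
        sprintf("psimif:%s(short label)", mt_clean(it$names$short_label))
      } else {
        "-"
      },
      alias = mt_join(aliases),
      taxid = mt_taxid(if (is.null(it)) NULL else it$organism),
      biorole = mt_join(mt_cv(p$biological_role)),
      exprole = mt_join(unlist(lapply(p$experimental_roles, mt_cv))),
      type = if (p$entity$kind == "candidate_set") {
        mt_join(mt_cv(p$entity$set$set_type))
      } else if (!is.null(it)) {
        mt_join(mt_cv(it$interactor_type))
      } else {
        "-"
      },
      xrefs = if (!is.null(it) && !is.null(it$xref) &&
                  length(it$xref$secondary) > 0L) {
        mt_join(vapply(it$xref$secondary, function(s) {
          sprintf("%s:%s", mt_clean(s$db), mt_clean(s$id))
        }, character(1)))
      } else {
        "-"
      },
      annot = mt_join(vapply(p$attributes, function(a) {
        sprintf("%s:%s", mt_clean(a$name), mt_clean(a$value %||% ""))
      }, character(1))),
      features = mt_join(mt_features(p)),
      stoich = mt_stoich(p),
      idmeth = mt_join(unlist(lapply(p$identification_methods, mt_cv)))
    )
  }
  a <- side(bp$a)
  b <- side(bp$b)
  det <- mt_join(unlist(lapply(experiments, function(ex) {
    mt_cv(ex$interaction_detection_method)
  })))
  pubs <- mt_join(unlist(lapply(experiments, function(ex) {
    if (!is.null(ex$bibref$xref)) {
      sprintf("%s:%s", mt_clean(ex$bibref$xref$primary$db),
              mt_clean(ex$bibref$xref$primary$id))
    } else {
      character(0)
    }
  })))
  hosts <- mt_join(unlist(lapply(experiments, function(ex) {
    vapply(ex$host_organisms, mt_taxid, character(1))
  })))
  cells <- c(
    a$id, b$id, a$alt, b$alt, a$alias, b$alias,
    det, "-", pubs, a$taxid, b$taxid,
    mt_join(unlist(lapply(ia$interaction_types, mt_cv))),
    sprintf("psimif:%s", source_db),
    mt_xref_primary(ia$xref, sprintf("interaction-%d", ia$id)),
    mt_join(vapply(ia$confidences, function(cf) {
      sprintf("%s:%s", mt_clean(cf$unit$short_label %||% "score"),
              mt_clean(cf$value))
    }, character(1))),
    if (bp$expansion == "spoke") 'psi-mi:"MI:1060"(spoke expansion)' else "-",
    a$biorole, b$biorole, a$exprole, b$exprole, a$type, b$type,
    a$xrefs, b$xrefs, "-",
    a$annot, b$annot,
    mt_join(vapply(ia$attributes, function(at) {
      sprintf("%s:%s", mt_clean(at$name), mt_clean(at$value %||% ""))
    }, character(1))),
    hosts,
    mt_join(vapply(ia$parameters, function(pm) {
      sprintf("%s:%sx%d^%d", mt_clean(pm$term),
              num_lex(pm$factor, pm$factor_lexical), pm$base, pm$exponent)
    }, character(1))),
    "-", "-", "-", "-", "-",
    if (isTRUE(ia$negative)) "true" else "false",
    a$features, b$features, a$stoich, b$stoich, a$idmeth, b$idmeth
  )
  paste(cells, collapse = "\t")
}
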