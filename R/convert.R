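# Lossy 3.0 -> 2.5 downgrade and promoting 2.5 -> 3.0 upgrade.
#
# Every 3.0-only construct is (a) re-expressed with the documented 2.5
# workaround so that plain 2.5 consumers see something useful, and (b)
# preserved verbatim as an XML snippet inside a "psimi3:"-prefixed
# attribute, so that upgrade(promote = TRUE) can restore it exactly.  One
# LossReport item is recorded per transformed construct.

LOSS_CATEGORIES <- c("NEGATIVE_POSITION", "RESULTING_SEQUENCE",
                     "EXTRA_DETECTION_METHODS", "FEATURE_ROLE",
                     "FEATURE_PARAMETERS", "VARIABLE_PARAMETERS",
                     "ABSTRACT_INTERACTION", "COOPERATIVE_EFFECT",
                     "CANDIDATE_SET", "STOICHIOMETRY_ELEMENT",
                     "BIBREF_SPLIT")

A3 <- list(
  range = "psimi3:feature-range",
  resseq = "psimi3:resulting-sequence",
  detect = "psimi3:feature-detection-method",
  role = "psimi3:feature-role",
  fparam = "psimi3:feature-parameter",
  varparam = "psimi3:variable-parameter",
  varvalues = "psimi3:variable-values",
  abstract = "psimi3:abstract-interaction",
  coop = "psimi3:cooperative-effect",
  candidates = "psimi3:interactor-candidate-list",
  placeholder = "psimi3:candidate-set-placeholder",
  stoich = "psimi3:stoichiometry",
  bibattr = "psimi3:bibref-attribute",
  synthexp = "psimi3:synthesized-experiment"
)

undetermined_cv <- function() {
  mif_cv("undetermined", mi_accession = "MI:0339")
}

# ---- 3.0-only construct scan (independent of the downgrade itself) ---------

# one record per construct a downgrade would have to transform; candidate
# sets are counted as single constructs (their inner features ride along in
# the preserved snippet)
scan_30_constructs <- function(doc) {
  items <- list()
  add <- function(category, path, detail = "") {
    items[[length(items) + 1L]] <<- list(category = category, path = path,
                                         detail = detail)
  }
  scan_feature <- function(f, path) {
    for (ri in seq_along(f$ranges)) {
      r <- f$ranges[[ri]]
      rpath <- sprintf("%s/ranges[%d]", path, ri)
      if (!is.null(r$resulting_sequence)) {
        add("RESULTING_SEQUENCE", rpath, "resulting sequence")
      }
      vals <- c(position_values(r$begin), position_values(r$end))
      if (any(vals <= 0L)) {
        add("NEGATIVE_POSITION", rpath,
            sprintf("coordinates %s", paste(vals[vals <= 0L], collapse = ",")))
      }
    }
    if (length(f$detection_methods) > 1L) {
      add("EXTRA_DETECTION_METHODS", path,
          sprintf("%d methods", length(f$detection_methods)))
    }
    if (!is.null(f$feature_role)) add("FEATURE_ROLE", path, "feature role")
    if (length(f$parameters) > 0L) {
      add("FEATURE_PARAMETERS", path,
          sprintf("%d parameter(s)", length(f$parameters)))
    }
  }
  scan_participant <- function(p, path) {
    if (p$entity$kind == "candidate_set") {
      add("CANDIDATE_SET", path,
          sprintf("%d candidate(s)", length(p$entity$set$candidates)))
    }
    if (p$stoichiometry$kind != "unstated") {
      add("STOICHIOMETRY_ELEMENT", path, p$stoichiometry$kind)
    }
    for (fi in seq_along(p$features)) {
      scan_feature(p$features[[fi]], sprintf("%s/features[%d]", path, fi))
    }
  }
  for (ei in seq_along(doc$entries)) {
    entry <- doc$entries[[ei]]
    epath <- sprintf("entries[%d]", ei)
    for (xi in seq_along(entry$experiments)) {
      ex <- entry$experiments[[xi]]
      xpath <- sprintf("%s/experiments[%d]", epath, xi)
      for (vi in seq_along(ex$variable_parameters)) {
        add("VARIABLE_PARAMETERS",
            sprintf("%s/variableParameter[%d]", xpath, vi),
            ex$variable_parameters[[vi]]$description)
      }
      if (!is.null(ex$bibref) && !is.null(ex$bibref$xref) &&
          length(ex$bibref$attributes) > 0L) {
        add("BIBREF_SPLIT", paste0(xpath, "/bibref"),
            sprintf("%d attribute(s)", length(ex$bibref$attributes)))
      }
    }
    for (ii in seq_along(entry$interactions)) {
      ia <- entry$interactions[[ii]]
      ipath <- sprintf("%s/interactions[%d]", epath, ii)
      if (inherits(ia, "mif_abstract_interaction")) {
        add("ABSTRACT_INTERACTION", ipath,
            ia$names$short_label %||% "abstract interaction")
        for (ci in seq_along(ia$cooperative_effects)) {
          add("COOPERATIVE_EFFECT",
              sprintf("%s/cooperativeEffect[%d]", ipath, ci),
              ia$cooperative_effects[[ci]]$kind)
        }
      } else if (length(ia$condition_sets) > 0L) {
        add("VARIABLE_PARAMETERS", ipath,
            sprintf("%d condition set(s)", length(ia$condition_sets)))
      }
      for (pi in seq_along(ia$participants)) {
        scan_participant(ia$participants[[pi]],
                         sprintf("%s/participants[%d]", ipath, pi))
      }
    }
  }
  items
}

new_loss_report <- function(items = list()) {
  structure(list(items = items), class = "mif_loss_report")
}

#' @export
print.mif_loss_report <- function(x, ...) {
  if (length(x$items) == 0L) {
    cat("<loss report: empty (no 3.0-only content)>\n")
    return(invisible(x))
  }
  cat(sprintf("<loss report: %d item(s)>\n", length(x$items)))
  tb <- mif_loss_categories(x)
  for (nm in names(tb)) cat(sprintf("  %-24s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Category counts of a loss report
#' @param report A `mif_loss_report`.
#' @return Named integer vector (category -> count), categories with zero
#'   items omitted.
#' @export
mif_loss_categories <- function(report) {
  cats <- vapply(report$items, function(it) it$category, character(1))
  tb <- table(factor(cats, levels = LOSS_CATEGORIES))
  out <- as.integer(tb)
  names(out) <- names(tb)
  out[out > 0L]
}

#' Serialize a loss report to JSON
#' @param report A `mif_loss_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
mif_loss_report_json <- function(report, path = NULL) {
  txt <- as.character(jsonlite::toJSON(
    list(n_items = length(report$items),
         categories = as.list(mif_loss_categories(report)),
         items = lapply(report$items, function(it) {
           list(category = it$category, path = it$path, detail = it$detail)
         })),
    auto_unbox = TRUE, pretty = TRUE))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# ---- downgrade --------------------------------------------------------------

mark <- function(name, value) mif_attribute(name = name, value = value)

downgrade_feature <- function(f, path, ctx) {
  moved <- list()
  for (ri in seq_along(f$ranges)) {
    r <- f$ranges[[ri]]
    rpath <- sprintf("%s/ranges[%d]", path, ri)
    if (!is.null(r$resulting_sequence)) {
      rs <- r$resulting_sequence
      ctx$report("RESULTING_SEQUENCE", rpath, "moved to feature attribute")
      f$attributes <- c(f$attributes, list(mark(
        A3$resseq, sprintf("%d|%s", ri, mif_snippet(rs)))))
      # visible workaround: the change as text, the xref on the feature
      f$attributes <- c(f$attributes, list(mif_attribute(
        "resulting sequence",
        sprintf("%s->%s", rs$original %||% "?", rs$new %||% "?"))))
      if (!is.null(rs$xref)) {
        if (is.null(f$xref)) {
          f$xref <- rs$xref
        } else {
          f$xref$secondary <- c(f$xref$secondary, list(rs$xref$primary),
                                rs$xref$secondary)
        }
      }
      r$resulting_sequence <- NULL
      f$ranges[[ri]] <- r
    }
    vals <- c(position_values(r$begin), position_values(r$end))
    if (any(vals <= 0L)) {
      ctx$report("NEGATIVE_POSITION", rpath,
                 "coordinates preserved in feature attribute")
      r_snip <- f$ranges[[ri]]       # after resulting-sequence removal
      f$attributes <- c(f$attributes, list(mark(
        A3$range, sprintf("%d|%s", ri, mif_snippet(r_snip)))))
      r$begin_status <- undetermined_cv()
      r$end_status <- undetermined_cv()
      r$begin <- mif_pos_unstated()
      r$end <- mif_pos_unstated()
      r$resulting_sequence <- NULL
      f$ranges[[ri]] <- r
    }
  }
  if (length(f$detection_methods) > 1L) {
    ctx$report("EXTRA_DETECTION_METHODS", path,
               "methods beyond the first moved to attributes")
    for (m in f$detection_methods[-1L]) {
      f$attributes <- c(f$attributes, list(mark(
        A3$detect, mif_snippet(m, tag = "featureDetectionMethod"))))
    }
    f$detection_methods <- f$detection_methods[1L]
  }
  if (!is.null(f$feature_role)) {
    ctx$report("FEATURE_ROLE", path, "moved to feature attribute")
    f$attributes <- c(f$attributes, list(mark(
      A3$role, mif_snippet(f$feature_role, tag = "featureRole"))))
    f$feature_role <- NULL
  }
  if (length(f$parameters) > 0L) {
    ctx$report("FEATURE_PARAMETERS", path,
               "moved to the interaction parameter list")
    for (pm in f$parameters) {
      moved[[length(moved) + 1L]] <- list(fid = f$id, param = pm)
    }
    f$parameters <- list()
  }
  list(feature = f, moved = moved)
}

downgrade_participant <- function(p, path, ctx) {
  moved <- list()
  if (p$entity$kind == "candidate_set") {
    set <- p$entity$set
    ctx$report("CANDIDATE_SET", path,
               "collapsed to a molecule-set interactor")
    p$attributes <- c(p$attributes, list(mark(
      A3$candidates, mif_snippet(set))))
    labels <- vapply(set$candidates, function(cand) {
      it <- ctx$interactor_index[[as.character(cand$interactor_ref)]]
      (it$names$short_label %||% NULL) %||%
        sprintf("candidate-%d", cand$id)
    }, character(1))
    refs <- lapply(labels, function(lb) mif_dbref(db = "psimif-candidate",
                                                  id = lb))
    pid <- ctx$next_id()
    placeholder <- mif_interactor(
      id = pid,
      interactor_type = set$set_type,
      names = mif_names(short_label = paste(labels, collapse = "/")),
      xref = mif_xref(refs[[1L]], refs[-1L]),
      attributes = list(mark(A3$placeholder, "true"))
    )
    ctx$add_interactor(placeholder)
    p$entity <- mif_entity(interactor_ref = pid)
  }
  if (p$stoichiometry$kind == "mean") {
    ctx$report("STOICHIOMETRY_ELEMENT", path, "moved to participant attribute")
    p$attributes <- c(p$attributes, list(mark(
      A3$stoich,
      paste0("mean|", num_lex(p$stoichiometry$value,
                              p$stoichiometry$value_lexical)))))
    p$stoichiometry <- mif_stoich_unstated()
  } else if (p$stoichiometry$kind == "range") {
    ctx$report("STOICHIOMETRY_ELEMENT", path, "moved to participant attribute")
    p$attributes <- c(p$attributes, list(mark(
      A3$stoich,
      sprintf("range|%s|%s",
              num_lex(p$stoichiometry$min_value, p$stoichiometry$min_lexical),
              num_lex(p$stoichiometry$max_value, p$stoichiometry$max_lexical)))))
    p$stoichiometry <- mif_stoich_unstated()
  }
  for (fi in seq_along(p$features)) {
    res <- downgrade_feature(p$features[[fi]],
                             sprintf("%s/features[%d]", path, fi), ctx)
    p$features[[fi]] <- res$feature
    moved <- c(moved, res$moved)
  }
  list(participant = p, moved = moved)
}

attach_moved_params <- function(ia, moved) {
  for (mv in moved) {
    pm <- mv$param
    ia$attributes <- c(ia$attributes, list(mark(
      A3$fparam, sprintf("%d|%s", mv$fid, mif_snippet(pm)))))
    ia$parameters <- c(ia$parameters, list(pm))
  }
  ia
}

downgrade_abstract <- function(ia, path, ctx) {
  ctx$report("ABSTRACT_INTERACTION", path,
             "converted to a 2.5 interaction with a synthesized experiment")
  snippet <- mif_snippet(ia)
  attrs <- c(ia$attributes, list(mark(A3$abstract, snippet)))
  for (ci in seq_along(ia$cooperative_effects)) {
    eff <- ia$cooperative_effects[[ci]]
    ctx$report("COOPERATIVE_EFFECT",
               sprintf("%s/cooperativeEffect[%d]", path, ci),
               "re-expressed as interaction-level annotation")
    attrs <- c(attrs, list(mif_attribute(
      A3$coop,
      sprintf("%s; outcome %s; affects interaction(s) %s", eff$kind,
              eff$outcome$short_label %||% eff$outcome$mi_accession,
              paste(eff$affected_refs, collapse = ",")))))
  }
  exp_id <- ctx$next_id()
  bib <- if (!is.null(ia$xref)) {
    mif_bibref(xref = ia$xref)
  } else {
    mif_bibref(attributes = list(mif_attribute(
      "psimi3:synthesized-bibref", "modelled interaction; no primary reference")))
  }
  synth <- mif_experiment(
    id = exp_id, bibref = bib,
    interaction_detection_method = mif_cv("inferred by curator",
                                          mi_accession = "MI:0364"),
    attributes = list(mark(A3$synthexp, "true")))
  ctx$add_experiment(synth)
  moved_all <- list()
  participants <- ia$participants
  for (pi in seq_along(participants)) {
    res <- downgrade_participant(participants[[pi]],
                                 sprintf("%s/participants[%d]", path, pi),
                                 ctx)
    participants[[pi]] <- res$participant
    moved_all <- c(moved_all, res$moved)
  }
  out <- mif_interaction(
    id = ia$id, names = ia$names, xref = ia$xref,
    experiment_refs = exp_id,
    participants = participants,
    interaction_types = if (is.null(ia$interaction_type)) list() else
      list(ia$interaction_type),
    attributes = attrs
  )
  attach_moved_params(out, moved_all)
}

#' Downgrade a 3.0 document to level 2.5
#'
#' Applies the documented 2.5 workaround for every 3.0-only construct and
#' records each transformation in a loss report: negative or zero
#' coordinates become undetermined ranges with the original range kept in a
#' feature attribute; resulting sequences, extra detection methods and
#' feature roles become feature attributes (the resulting-sequence xref is
#' also copied to the feature xref); feature-level parameters move to the
#' interaction parameter list; variable parameters and condition sets
#' become experiment / interaction attributes; an abstract interaction
#' becomes a 2.5 interaction whose synthesized experiment is detected by
#' "inferred by curator" (MI:0364), with cooperative effects re-expressed
#' as interaction-level annotations; a candidate set collapses to a single
#' molecule-set interactor carrying the candidates as xrefs; stoichiometry
#' moves to a participant attribute; a bibref holding both an xref and
#' attributes keeps the xref, its attributes moving to the experiment.
#'
#' Each transformed construct is also preserved verbatim in a
#' `psimi3:`-prefixed attribute so [mif_upgrade()] with `promote = TRUE`
#' can restore it.  The downgrade is total on validator-clean input.
#'
#' @param doc A [mif_document()] (level 3.0).
#' @return A list with `document` (level 2.5) and `report`
#'   (`mif_loss_report`).
#' @export
mif_downgrade <- function(doc) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  assert_resolved(doc)
  items <- list()
  doc$entries <- lapply(seq_along(doc$entries), function(ei) {
    entry <- doc$entries[[ei]]
    epath <- sprintf("entries[%d]", ei)
    id_counter <- new.env(parent = emptyenv())
    id_counter$n <- max(c(0L, entry_defined_ids(entry)))
    new_experiments <- new.env(parent = emptyenv())
    new_experiments$x <- list()
    new_interactors <- new.env(parent = emptyenv())
    new_interactors$x <- list()
    interactor_index <- list()
    for (it in entry$interactors) interactor_index[[as.character(it$id)]] <- it
    ctx <- list(
      report = function(category, path, detail) {
        items[[length(items) + 1L]] <<- list(category = category,
                                             path = path, detail = detail)
      },
      next_id = function() {
        id_counter$n <- id_counter$n + 1L
        id_counter$n
      },
      add_experiment = function(ex) {
        new_experiments$x <- c(new_experiments$x, list(ex))
      },
      add_interactor = function(it) {
        new_interactors$x <- c(new_interactors$x, list(it))
      },
      interactor_index = interactor_index
    )
    # experiments: bibref split + variable parameters
    entry$experiments <- lapply(seq_along(entry$experiments), function(xi) {
      ex <- entry$experiments[[xi]]
      xpath <- sprintf("%s/experiments[%d]", epath, xi)
      if (!is.null(ex$bibref$xref) && length(ex$bibref$attributes) > 0L) {
        ctx$report("BIBREF_SPLIT", paste0(xpath, "/bibref"),
                   "publication attributes moved to the experiment")
        for (a in ex$bibref$attributes) {
          ex$attributes <- c(ex$attributes,
                             list(mark(A3$bibattr, mif_snippet(a))),
                             list(a))
        }
        ex$bibref$attributes <- list()
      }
      for (vi in seq_along(ex$variable_parameters)) {
        vp <- ex$variable_parameters[[vi]]
        ctx$report("VARIABLE_PARAMETERS",
                   sprintf("%s/variableParameter[%d]", xpath, vi),
                   vp$description)
        ex$attributes <- c(ex$attributes,
                           list(mark(A3$varparam, mif_snippet(vp))))
      }
      ex$variable_parameters <- list()
      ex
    })
    # interactions
    entry$interactions <- lapply(seq_along(entry$interactions), function(ii) {
      ia <- entry$interactions[[ii]]
      ipath <- sprintf("%s/interactions[%d]", epath, ii)
      if (inherits(ia, "mif_abstract_interaction")) {
        return(downgrade_abstract(ia, ipath, ctx))
      }
      if (length(ia$condition_sets) > 0L) {
        ctx$report("VARIABLE_PARAMETERS", ipath,
                   "condition sets moved to interaction attributes")
        for (s in ia$condition_sets) {
          ia$attributes <- c(ia$attributes, list(mark(
            A3$varvalues, paste(s, collapse = ","))))
        }
        ia$condition_sets <- list()
      }
      moved_all <- list()
      for (pi in seq_along(ia$participants)) {
        res <- downgrade_participant(ia$participants[[pi]],
                                     sprintf("%s/participants[%d]",
                                             ipath, pi), ctx)
        ia$participants[[pi]] <- res$participant
        moved_all <- c(moved_all, res$moved)
      }
      attach_moved_params(ia, moved_all)
    })
    entry$experiments <- c(entry$experiments, new_experiments$x)
    entry$interactors <- c(entry$interactors, new_interactors$x)
    entry
  })
  doc$level <- "2.5"
  list(document = doc, report = new_loss_report(items))
}

# ---- upgrade ----------------------------------------------------------------

attr_name_is <- function(a, name) identical(a$name, name)

pop_attrs <- function(attrs, name) {
  hit <- vapply(attrs, attr_name_is, logical(1), name = name)
  list(values = lapply(attrs[hit], function(a) a$value),
       rest = attrs[!hit])
}

remove_one_attr <- function(attrs, target) {
  for (i in seq_along(attrs)) {
    a <- attrs[[i]]
    if (identical(a$name, target$name) &&
        identical(a$value, target$value) &&
        identical(a$name_ac, target$name_ac)) {
      return(attrs[-i])
    }
  }
  attrs
}

split_payload <- function(value) {
  k <- regexpr("|", value, fixed = TRUE)
  list(index = as.integer(substr(value, 1L, k - 1L)),
       body = substr(value, k + 1L, nchar(value)))
}

remove_dbref_once <- function(xref, target) {
  if (is.null(xref)) return(NULL)
  same <- function(r) identical(r$db, target$db) && identical(r$id, target$id)
  for (i in seq_along(xref$secondary)) {
    if (same(xref$secondary[[i]])) {
      xref$secondary <- xref$secondary[-i]
      return(xref)
    }
  }
  if (same(xref$primary)) {
    if (length(xref$secondary) > 0L) {
      xref$primary <- xref$secondary[[1L]]
      xref$secondary <- xref$secondary[-1L]
      return(xref)
    }
    return(NULL)
  }
  xref
}

promote_feature <- function(f) {
  pr <- pop_attrs(f$attributes, A3$range)
  f$attributes <- pr$rest
  for (v in pr$values) {
    sp <- split_payload(v)
    f$ranges[[sp$index]] <- mif_parse_snippet(sp$body)
  }
  pr <- pop_attrs(f$attributes, A3$resseq)
  f$attributes <- pr$rest
  for (v in pr$values) {
    sp <- split_payload(v)
    rs <- mif_parse_snippet(sp$body)
    f$ranges[[sp$index]]$resulting_sequence <- rs
    # undo the xref copied onto the feature and the readable text attribute
    if (!is.null(rs$xref)) {
      f$xref <- remove_dbref_once(f$xref, rs$xref$primary)
      for (s in rs$xref$secondary) f$xref <- remove_dbref_once(f$xref, s)
    }
    f$attributes <- remove_one_attr(f$attributes, mif_attribute(
      "resulting sequence",
      sprintf("%s->%s", rs$original %||% "?", rs$new %||% "?")))
  }
  pr <- pop_attrs(f$attributes, A3$detect)
  f$attributes <- pr$rest
  for (v in pr$values) {
    f$detection_methods <- c(f$detection_methods,
                             list(mif_parse_snippet(v)))
  }
  pr <- pop_attrs(f$attributes, A3$role)
  f$attributes <- pr$rest
  if (length(pr$values) > 0L) {
    f$feature_role <- mif_parse_snippet(pr$values[[1L]])
  }
  f
}

promote_participant <- function(p) {
  pr <- pop_attrs(p$attributes, A3$candidates)
  p$attributes <- pr$rest
  if (length(pr$values) > 0L) {
    p$entity <- mif_entity(candidate_set = mif_parse_snippet(pr$values[[1L]]))
  }
  pr <- pop_attrs(p$attributes, A3$stoich)
  p$attributes <- pr$rest
  if (length(pr$values) > 0L) {
    parts <- strsplit(pr$values[[1L]], "|", fixed = TRUE)[[1L]]
    p$stoichiometry <- if (parts[1L] == "mean") {
      mif_stoich_mean(as.numeric(parts[2L]), lexical = parts[2L])
    } else {
      mif_stoich_range(as.numeric(parts[2L]), as.numeric(parts[3L]),
                       min_lexical = parts[2L], max_lexical = parts[3L])
    }
  }
  p$features <- lapply(p$features, promote_feature)
  p
}

param_key <- function(pm) mif_snippet(pm)

promote_interaction <- function(ia) {
  # abstract interactions restore wholesale from their snapshot
  snap <- pop_attrs(ia$attributes, A3$abstract)
  if (length(snap$values) > 0L) {
    return(mif_parse_snippet(snap$values[[1L]]))
  }
  pr <- pop_attrs(ia$attributes, A3$varvalues)
  ia$attributes <- pr$rest
  for (v in pr$values) {
    ia$condition_sets <- c(ia$condition_sets,
                           list(as.integer(strsplit(v, ",")[[1L]])))
  }
  pr <- pop_attrs(ia$attributes, A3$fparam)
  ia$attributes <- pr$rest
  for (v in pr$values) {
    k <- regexpr("|", v, fixed = TRUE)
    fid <- as.integer(substr(v, 1L, k - 1L))
    pm <- mif_parse_snippet(substr(v, k + 1L, nchar(v)))
    key <- param_key(pm)
    for (i in seq_along(ia$parameters)) {
      if (param_key(ia$parameters[[i]]) == key) {
        ia$parameters <- ia$parameters[-i]
        break
      }
    }
    for (pi in seq_along(ia$participants)) {
      p <- ia$participants[[pi]]
      for (fi in seq_along(p$features)) {
        if (p$features[[fi]]$id == fid) {
          p$features[[fi]]$parameters <-
            c(p$features[[fi]]$parameters, list(pm))
        }
      }
      ia$participants[[pi]] <- p
    }
  }
  ia$participants <- lapply(ia$participants, promote_participant)
  ia
}

promote_experiment <- function(ex) {
  pr <- pop_attrs(ex$attributes, A3$varparam)
  ex$attributes <- pr$rest
  for (v in pr$values) {
    ex$variable_parameters <- c(ex$variable_parameters,
                                list(mif_parse_snippet(v)))
  }
  pr <- pop_attrs(ex$attributes, A3$bibattr)
  ex$attributes <- pr$rest
  for (v in pr$values) {
    a <- mif_parse_snippet(v)
    ex$bibref$attributes <- c(ex$bibref$attributes, list(a))
    ex$attributes <- remove_one_attr(ex$attributes, a)
  }
  ex
}

has_marker <- function(obj, name) {
  any(vapply(obj$attributes, attr_name_is, logical(1), name = name))
}

#' Upgrade a 2.5 document to level 3.0
#'
#' The structural lift sets the document level to 3.0 and invents no
#' content.  With `promote = TRUE`, attributes written by
#' [mif_downgrade()] (recognizable by their `psimi3:` prefix) are promoted
#' back to first-class 3.0 elements: restored abstract interactions
#' replace their 2.5 stand-ins (whose synthesized experiments and
#' molecule-set placeholder interactors are removed once unreferenced),
#' and features, participants, experiments and interactions regain their
#' preserved constructs.
#'
#' @param doc A [mif_document()] at level 2.5.
#' @param promote Recognize downgrade-produced attributes (default FALSE).
#' @return A [mif_document()] at level 3.0.
#' @export
mif_upgrade <- function(doc, promote = FALSE) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  doc$level <- "3.0"
  if (!promote) return(doc)
  doc$entries <- lapply(doc$entries, function(entry) {
    entry$interactions <- lapply(entry$interactions, promote_interaction)
    entry$experiments <- lapply(entry$experiments, promote_experiment)
    # drop synthesized experiments and placeholder interactors once nothing
    # references them any more
    referenced <- unlist(lapply(entry_references(entry), function(r) r$id))
    entry$experiments <- Filter(function(ex) {
      !(has_marker(ex, A3$synthexp) && !ex$id %in% referenced)
    }, entry$experiments)
    entry$interactors <- Filter(function(it) {
      !(has_marker(it, A3$placeholder) && !it$id %in% referenced)
    }, entry$interactors)
    entry
  })
  doc
}
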