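# Deterministic XML emission.  The writer builds the document as text with
# a fixed element and attribute order, so identical objects serialize to
# identical bytes (UTF-8, two-space indentation).

MIF300_NS <- "http://psi.hupo.org/mi/mif300"
MIF25_NS <- "net:sf:psidev:mi"

el_line <- function(ind, tag, attrs = NULL, text = NULL, empty = is.null(text)) {
  a <- ""
  if (length(attrs)) {
    keep <- !vapply(attrs, is.null, logical(1))
    attrs <- attrs[keep]
    if (length(attrs)) {
      a <- paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                                     vapply(attrs, function(v) xesc(as.character(v)),
                                            character(1))),
                             collapse = " "))
    }
  }
  if (empty) {
    sprintf("%s<%s%s/>", ind, tag, a)
  } else {
    sprintf("%s<%s%s>%s</%s>", ind, tag, a, xesc(as.character(text)), tag)
  }
}

open_tag <- function(ind, tag, attrs = NULL) {
  sub("/>$", ">", el_line(ind, tag, attrs, empty = TRUE))
}
close_tag <- function(ind, tag) sprintf("%s</%s>", ind, tag)

# wrap children in <tag>...</tag>, or emit nothing if no children
wrap_if <- function(ind, tag, children) {
  if (length(children) == 0L) return(character(0))
  c(open_tag(ind, tag), children, close_tag(ind, tag))
}

w_names <- function(ind, nm) {
  if (is.null(nm)) return(character(0))
  kids <- character(0)
  i2 <- paste0(ind, "  ")
  if (!is.null(nm$short_label)) kids <- c(kids, el_line(i2, "shortLabel", text = nm$short_label))
  if (!is.null(nm$full_name)) kids <- c(kids, el_line(i2, "fullName", text = nm$full_name))
  for (al in nm$aliases) kids <- c(kids, el_line(i2, "alias", text = al))
  wrap_if(ind, "names", kids)
}

w_dbref <- function(ind, tag, r) {
  el_line(ind, tag, attrs = list(db = r$db, dbAc = r$db_ac, id = r$id,
                                 version = r$version, refType = r$ref_type,
                                 refTypeAc = r$ref_type_ac))
}

w_xref <- function(ind, x) {
  if (is.null(x)) return(character(0))
  i2 <- paste0(ind, "  ")
  kids <- w_dbref(i2, "primaryRef", x$primary)
  for (s in x$secondary) kids <- c(kids, w_dbref(i2, "secondaryRef", s))
  wrap_if(ind, "xref", kids)
}

synthesized_dbref <- function(acc) {
  mif_dbref(db = "psi-mi", db_ac = "MI:0488", id = acc,
            ref_type = "identity", ref_type_ac = "MI:0356")
}

cv_effective_xref <- function(cv) {
  if (is.null(cv$xref)) {
    if (is.null(cv$mi_accession)) return(NULL)
    return(mif_xref(synthesized_dbref(cv$mi_accession)))
  }
  x <- cv$xref
  if (!is.null(cv$mi_accession)) {
    has_acc <- identical(x$primary$db, "psi-mi") &&
      identical(x$primary$id, cv$mi_accession)
    if (!has_acc) {
      for (s in x$secondary) {
        if (identical(s$db, "psi-mi") && identical(s$id, cv$mi_accession)) {
          has_acc <- TRUE
          break
        }
      }
    }
    if (!has_acc) {
      x$secondary <- c(x$secondary, list(synthesized_dbref(cv$mi_accession)))
    }
  }
  x
}

w_cv <- function(ind, tag, cv) {
  if (is.null(cv)) return(character(0))
  i2 <- paste0(ind, "  ")
  nm_kids <- character(0)
  if (!is.null(cv$short_label)) {
    nm_kids <- c(nm_kids, el_line(paste0(i2, "  "), "shortLabel",
                                  text = cv$short_label))
  }
  if (!is.null(cv$full_name)) {
    nm_kids <- c(nm_kids, el_line(paste0(i2, "  "), "fullName",
                                  text = cv$full_name))
  }
  kids <- wrap_if(i2, "names", nm_kids)
  kids <- c(kids, w_xref(i2, cv_effective_xref(cv)))
  c(open_tag(ind, tag), kids, close_tag(ind, tag))
}

w_attribute <- function(ind, a) {
  attrs <- list(name = a$name, nameAc = a$name_ac)
  if (is.null(a$value)) {
    el_line(ind, "attribute", attrs = attrs, text = "", empty = FALSE)
  } else {
    el_line(ind, "attribute", attrs = attrs, text = a$value)
  }
}

w_attributes <- function(ind, attrs) {
  i2 <- paste0(ind, "  ")
  wrap_if(ind, "attributeList",
          unlist(lapply(attrs, function(a) w_attribute(i2, a))))
}

w_bibref <- function(ind, b) {
  if (is.null(b)) return(character(0))
  i2 <- paste0(ind, "  ")
  kids <- c(w_xref(i2, b$xref), w_attributes(i2, b$attributes))
  c(open_tag(ind, "bibref"), kids, close_tag(ind, "bibref"))
}

w_organism <- function(ind, tag, org) {
  if (is.null(org)) return(character(0))
  i2 <- paste0(ind, "  ")
  kids <- c(w_names(i2, org$names),
            w_cv(i2, "cellType", org$cell_type),
            w_cv(i2, "compartment", org$compartment),
            w_cv(i2, "tissue", org$tissue))
  if (length(kids) == 0L) {
    el_line(ind, tag, attrs = list(ncbiTaxId = org$ncbi_tax_id))
  } else {
    c(open_tag(ind, tag, attrs = list(ncbiTaxId = org$ncbi_tax_id)),
      kids, close_tag(ind, tag))
  }
}

w_parameter <- function(ind, p) {
  attrs <- list(term = p$term, termAc = p$term_ac, unit = p$unit,
                unitAc = p$unit_ac, base = p$base, exponent = p$exponent,
                factor = num_lex(p$factor, p$factor_lexical))
  if (!is.null(p$uncertainty)) attrs$uncertainty <- num_lex(p$uncertainty)
  if (is.null(p$experiment_ref)) {
    el_line(ind, "parameter", attrs = attrs)
  } else {
    c(open_tag(ind, "parameter", attrs = attrs),
      el_line(paste0(ind, "  "), "experimentRef", text = p$experiment_ref),
      close_tag(ind, "parameter"))
  }
}

w_parameters <- function(ind, params) {
  i2 <- paste0(ind, "  ")
  wrap_if(ind, "parameterList",
          unlist(lapply(params, function(p) w_parameter(i2, p))))
}

w_confidences <- function(ind, confs) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  kids <- unlist(lapply(confs, function(cf) {
    c(open_tag(i2, "confidence"),
      w_cv(i3, "unit", cf$unit),
      el_line(i3, "value", text = cf$value),
      close_tag(i2, "confidence"))
  }))
  wrap_if(ind, "confidenceList", kids)
}

w_variable_parameter <- function(ind, vp) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  vals <- unlist(lapply(vp$values, function(vv) {
    el_line(i3, "variableValue",
            attrs = list(id = vv$id, order = vv$order), text = vv$value)
  }))
  c(open_tag(ind, "variableParameter"),
    el_line(i2, "description", text = vp$description),
    w_cv(i2, "unit", vp$unit),
    wrap_if(i2, "variableValueList", vals),
    close_tag(ind, "variableParameter"))
}

w_experiment <- function(ind, ex) {
  i2 <- paste0(ind, "  ")
  kids <- c(
    w_names(i2, ex$names),
    w_bibref(i2, ex$bibref),
    w_xref(i2, ex$xref),
    wrap_if(i2, "hostOrganismList",
            unlist(lapply(ex$host_organisms, function(o) {
              w_organism(paste0(i2, "  "), "hostOrganism", o)
            }))),
    w_cv(i2, "interactionDetectionMethod", ex$interaction_detection_method),
    w_cv(i2, "participantIdentificationMethod",
         ex$participant_identification_method),
    w_cv(i2, "featureDetectionMethod", ex$feature_detection_method),
    wrap_if(i2, "variableParameterList",
            unlist(lapply(ex$variable_parameters, function(vp) {
              w_variable_parameter(paste0(i2, "  "), vp)
            }))),
    w_confidences(i2, ex$confidences),
    w_attributes(i2, ex$attributes)
  )
  c(open_tag(ind, "experimentDescription", attrs = list(id = ex$id)),
    kids, close_tag(ind, "experimentDescription"))
}

w_interactor <- function(ind, it) {
  i2 <- paste0(ind, "  ")
  kids <- c(
    w_names(i2, it$names),
    w_xref(i2, it$xref),
    w_cv(i2, "interactorType", it$interactor_type),
    w_organism(i2, "organism", it$organism),
    if (!is.null(it$sequence)) el_line(i2, "sequence", text = it$sequence),
    w_attributes(i2, it$attributes)
  )
  c(open_tag(ind, "interactor", attrs = list(id = it$id)),
    kids, close_tag(ind, "interactor"))
}

w_position_pair <- function(ind, r) {
  out <- w_cv(ind, "startStatus", r$begin_status)
  out <- c(out, w_position(ind, r$begin, "begin", "beginInterval"))
  out <- c(out, w_cv(ind, "endStatus", r$end_status))
  c(out, w_position(ind, r$end, "end", "endInterval"))
}

w_position <- function(ind, pos, tag_exact, tag_interval) {
  switch(pos$kind,
    exact = el_line(ind, tag_exact, attrs = list(position = pos$value)),
    interval = el_line(ind, tag_interval,
                       attrs = list(begin = pos$start, end = pos$end)),
    unstated = character(0)
  )
}

w_resulting_sequence <- function(ind, rs) {
  if (is.null(rs)) return(character(0))
  i2 <- paste0(ind, "  ")
  kids <- c(
    if (!is.null(rs$original)) el_line(i2, "originalSequence", text = rs$original),
    if (!is.null(rs$new)) el_line(i2, "newSequence", text = rs$new),
    w_xref(i2, rs$xref)
  )
  c(open_tag(ind, "resultingSequence"), kids,
    close_tag(ind, "resultingSequence"))
}

w_feature_range <- function(ind, r, level) {
  i2 <- paste0(ind, "  ")
  kids <- w_position_pair(i2, r)
  if (isTRUE(r$is_link)) kids <- c(kids, el_line(i2, "isLink", text = "true"))
  if (level == "3.0") kids <- c(kids, w_resulting_sequence(i2, r$resulting_sequence))
  c(open_tag(ind, "featureRange"), kids, close_tag(ind, "featureRange"))
}

w_feature <- function(ind, f, level = "3.0") {
  i2 <- paste0(ind, "  ")
  kids <- c(
    w_names(i2, f$names),
    w_xref(i2, f$xref),
    w_cv(i2, "featureType", f$feature_type),
    if (level == "3.0") w_cv(i2, "featureRole", f$feature_role),
    unlist(lapply(f$detection_methods, function(m) {
      w_cv(i2, "featureDetectionMethod", m)
    })),
    wrap_if(i2, "featureRangeList",
            unlist(lapply(f$ranges, function(r) {
              w_feature_range(paste0(i2, "  "), r, level)
            }))),
    if (level == "3.0") w_parameters(i2, f$parameters),
    w_attributes(i2, f$attributes)
  )
  c(open_tag(ind, "feature", attrs = list(id = f$id)),
    kids, close_tag(ind, "feature"))
}

w_candidate_set <- function(ind, set, ctx) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  kids <- w_cv(i2, "moleculeSetType", set$set_type)
  for (cand in set$candidates) {
    ckids <- w_entity_interactor(i3, cand$interactor_ref, ctx)
    ckids <- c(ckids,
               wrap_if(i3, "featureList",
                       unlist(lapply(cand$features, function(f) {
                         w_feature(paste0(i3, "  "), f, ctx$level)
                       }))))
    kids <- c(kids,
              open_tag(i2, "interactorCandidate", attrs = list(id = cand$id)),
              ckids, close_tag(i2, "interactorCandidate"))
  }
  c(open_tag(ind, "interactorCandidateList"), kids,
    close_tag(ind, "interactorCandidateList"))
}

# in compact form: always a ref; in extended form: inline on first use
w_entity_interactor <- function(ind, ref, ctx) {
  if (ctx$form == "compact" || ref %in% ctx$seen$interactors) {
    return(el_line(ind, "interactorRef", text = ref))
  }
  ctx$seen$interactors <- c(ctx$seen$interactors, ref)
  it <- ctx$interactor_index[[as.character(ref)]]
  if (is.null(it)) {          # dangling ref tolerated at write time
    return(el_line(ind, "interactorRef", text = ref))
  }
  w_interactor(ind, it)
}

w_participant <- function(ind, p, ctx) {
  i2 <- paste0(ind, "  ")
  entity <- switch(p$entity$kind,
    interactor_ref = w_entity_interactor(i2, p$entity$ref, ctx),
    interaction_ref = el_line(i2, "interactionRef", text = p$entity$ref),
    candidate_set = w_candidate_set(i2, p$entity$set, ctx)
  )
  level <- ctx$level
  kids <- c(
    w_names(i2, p$names),
    w_xref(i2, p$xref),
    entity,
    wrap_if(i2, "participantIdentificationMethodList",
            unlist(lapply(p$identification_methods, function(m) {
              w_cv(paste0(i2, "  "), "participantIdentificationMethod", m)
            }))),
    w_cv(i2, "biologicalRole", p$biological_role),
    wrap_if(i2, "experimentalRoleList",
            unlist(lapply(p$experimental_roles, function(r) {
              w_cv(paste0(i2, "  "), "experimentalRole", r)
            }))),
    wrap_if(i2, "experimentalPreparationList",
            unlist(lapply(p$experimental_preparations, function(r) {
              w_cv(paste0(i2, "  "), "experimentalPreparation", r)
            }))),
    wrap_if(i2, "featureList",
            unlist(lapply(p$features, function(f) {
              w_feature(paste0(i2, "  "), f, level)
            }))),
    wrap_if(i2, "hostOrganismList",
            unlist(lapply(p$host_organisms, function(o) {
              w_organism(paste0(i2, "  "), "hostOrganism", o)
            }))),
    w_confidences(i2, p$confidences),
    w_parameters(i2, p$parameters),
    if (level == "3.0" && p$stoichiometry$kind == "mean") {
      el_line(i2, "stoichiometry",
              attrs = list(value = num_lex(p$stoichiometry$value,
                                           p$stoichiometry$value_lexical)))
    } else if (level == "3.0" && p$stoichiometry$kind == "range") {
      el_line(i2, "stoichiometryRange",
              attrs = list(
                minValue = num_lex(p$stoichiometry$min_value,
                                   p$stoichiometry$min_lexical),
                maxValue = num_lex(p$stoichiometry$max_value,
                                   p$stoichiometry$max_lexical)))
    },
    w_attributes(i2, p$attributes)
  )
  c(open_tag(ind, "participant", attrs = list(id = p$id)),
    kids, close_tag(ind, "participant"))
}

w_experiment_refs <- function(ind, refs, ctx) {
  i2 <- paste0(ind, "  ")
  kids <- unlist(lapply(refs, function(ref) {
    if (ctx$form == "compact" || ref %in% ctx$seen$experiments) {
      el_line(i2, "experimentRef", text = ref)
    } else {
      ctx$seen$experiments <- c(ctx$seen$experiments, ref)
      ex <- ctx$experiment_index[[as.character(ref)]]
      if (is.null(ex)) {
        el_line(i2, "experimentRef", text = ref)
      } else {
        w_experiment(i2, ex)
      }
    }
  }))
  wrap_if(ind, "experimentList", kids)
}

w_inferred <- function(ind, groups) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  i4 <- paste0(i3, "  ")
  kids <- unlist(lapply(groups, function(g) {
    items <- unlist(lapply(g, function(item) {
      tag <- if (identical(item$kind, "feature")) "participantFeatureRef"
             else "participantRef"
      c(open_tag(i3, "participant"),
        el_line(i4, tag, text = item$ref),
        close_tag(i3, "participant"))
    }))
    c(open_tag(i2, "inferredInteraction"), items,
      close_tag(i2, "inferredInteraction"))
  }))
  wrap_if(ind, "inferredInteractionList", kids)
}

w_interaction <- function(ind, ia, ctx) {
  i2 <- paste0(ind, "  ")
  kids <- c(
    w_names(i2, ia$names),
    w_xref(i2, ia$xref),
    w_experiment_refs(i2, ia$experiment_refs, ctx),
    wrap_if(i2, "participantList",
            unlist(lapply(ia$participants, function(p) {
              w_participant(paste0(i2, "  "), p, ctx)
            }))),
    w_inferred(i2, ia$inferred_interactions),
    unlist(lapply(ia$interaction_types, function(tp) {
      w_cv(i2, "interactionType", tp)
    })),
    if (isTRUE(ia$negative)) el_line(i2, "negative", text = "true"),
    if (isTRUE(ia$intra_molecular)) el_line(i2, "intraMolecular", text = "true"),
    w_confidences(i2, ia$confidences),
    w_parameters(i2, ia$parameters),
    if (ctx$level == "3.0") {
      unlist(lapply(ia$condition_sets, function(s) {
        refs <- unlist(lapply(s, function(id) {
          el_line(paste0(i2, "  "), "variableValueRef", text = id)
        }))
        c(open_tag(i2, "variableValueRefList"), refs,
          close_tag(i2, "variableValueRefList"))
      }))
    },
    w_attributes(i2, ia$attributes)
  )
  c(open_tag(ind, "interaction", attrs = list(id = ia$id)),
    kids, close_tag(ind, "interaction"))
}

w_coop_effect <- function(ind, eff) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  i4 <- paste0(i3, "  ")
  ev_kids <- unlist(lapply(eff$evidence, function(ev) {
    meth <- unlist(lapply(ev$methods, function(m) {
      w_cv(paste0(i4, "  "), "evidenceMethod", m)
    }))
    c(open_tag(i3, "cooperativeEffectEvidence"),
      w_bibref(i4, ev$bibref),
      wrap_if(i4, "evidenceMethodList", meth),
      close_tag(i3, "cooperativeEffectEvidence"))
  }))
  kids <- c(
    wrap_if(i2, "cooperativeEffectEvidenceList", ev_kids),
    wrap_if(i2, "affectedInteractionList",
            unlist(lapply(eff$affected_refs, function(r) {
              el_line(i3, "affectedInteractionRef", text = r)
            }))),
    w_cv(i2, "cooperativeEffectOutcome", eff$outcome),
    w_cv(i2, "cooperativeEffectResponse", eff$response)
  )
  if (eff$kind == "allostery") {
    kids <- c(kids,
      el_line(i2, "allostericMoleculeRef", text = eff$allosteric_molecule_ref),
      if (eff$effector$kind == "molecule") {
        el_line(i2, "moleculeEffectorRef", text = eff$effector$ref)
      } else {
        el_line(i2, "featureModificationEffectorRef", text = eff$effector$ref)
      },
      w_cv(i2, "allosteryType", eff$allostery_type),
      w_cv(i2, "allostericMechanism", eff$allosteric_mechanism))
  }
  c(open_tag(ind, eff$kind), kids, close_tag(ind, eff$kind))
}

w_abstract <- function(ind, ia, ctx) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  kids <- c(
    w_names(i2, ia$names),
    w_xref(i2, ia$xref),
    w_cv(i2, "interactorType", ia$interactor_type),
    w_cv(i2, "interactionType", ia$interaction_type),
    w_organism(i2, "organism", ia$organism),
    wrap_if(i2, "participantList",
            unlist(lapply(ia$participants, function(p) {
              w_participant(i3, p, ctx)
            }))),
    wrap_if(i2, "bindingFeatureList",
            unlist(lapply(ia$binding_features, function(s) {
              refs <- unlist(lapply(s, function(id) {
                el_line(paste0(i3, "  "), "participantFeatureRef", text = id)
              }))
              c(open_tag(i3, "bindingFeatures"), refs,
                close_tag(i3, "bindingFeatures"))
            }))),
    wrap_if(i2, "cooperativeEffectList",
            unlist(lapply(ia$cooperative_effects, function(e) {
              w_coop_effect(i3, e)
            }))),
    w_cv(i2, "evidenceType", ia$evidence_type),
    w_attributes(i2, ia$attributes)
  )
  c(open_tag(ind, "abstractInteraction", attrs = list(id = ia$id)),
    kids, close_tag(ind, "abstractInteraction"))
}

w_source <- function(ind, src) {
  if (is.null(src)) return(character(0))
  i2 <- paste0(ind, "  ")
  kids <- c(w_names(i2, src$names), w_xref(i2, src$xref),
            w_bibref(i2, src$bibref), w_attributes(i2, src$attributes))
  attrs <- list(releaseDate = src$release_date)
  if (length(kids) == 0L) {
    el_line(ind, "source", attrs = attrs)
  } else {
    c(open_tag(ind, "source", attrs = attrs), kids, close_tag(ind, "source"))
  }
}

w_entry <- function(ind, entry, ctx) {
  i2 <- paste0(ind, "  ")
  i3 <- paste0(i2, "  ")
  ctx$experiment_index <- list()
  for (ex in entry$experiments) ctx$experiment_index[[as.character(ex$id)]] <- ex
  ctx$interactor_index <- list()
  for (it in entry$interactors) ctx$interactor_index[[as.character(it$id)]] <- it
  ctx$seen <- new.env(parent = emptyenv())
  ctx$seen$experiments <- integer(0)
  ctx$seen$interactors <- integer(0)

  interactions_xml <- unlist(lapply(entry$interactions, function(ia) {
    if (inherits(ia, "mif_interaction")) w_interaction(i3, ia, ctx)
    else w_abstract(i3, ia, ctx)
  }))

  if (ctx$form == "compact") {
    exp_list <- unlist(lapply(entry$experiments, function(e) w_experiment(i3, e)))
    int_list <- unlist(lapply(entry$interactors, function(it) w_interactor(i3, it)))
  } else {
    # extended form inlines at first use; emit only never-inlined orphans
    exp_list <- unlist(lapply(entry$experiments, function(e) {
      if (e$id %in% ctx$seen$experiments) character(0) else w_experiment(i3, e)
    }))
    int_list <- unlist(lapply(entry$interactors, function(it) {
      if (it$id %in% ctx$seen$interactors) character(0) else w_interactor(i3, it)
    }))
  }
  kids <- c(
    w_source(i2, entry$source),
    wrap_if(i2, "availabilityList",
            unlist(lapply(entry$availabilities, function(av) {
              el_line(i3, "availability", attrs = list(id = av$id),
                      text = av$value)
            }))),
    wrap_if(i2, "experimentList", exp_list),
    wrap_if(i2, "interactorList", int_list),
    wrap_if(i2, "interactionList", interactions_xml),
    w_attributes(i2, entry$attributes)
  )
  c(open_tag(ind, "entry"), kids, close_tag(ind, "entry"))
}

#' Write a PSI-MI XML document
#'
#' Serializes a document in the compact form (repeated experiments and
#' interactors defined once in entry-level lists, the default — designed
#' for larger datasets) or the extended form (related data inlined at first
#' use, designed for easy parsing).  Output is UTF-8 with canonical element
#' and attribute order, so serialization is byte-reproducible.
#'
#' A document at level 2.5 that still carries 3.0-only content (negative
#' positions, resulting sequences, variable parameters, abstract
#' interactions, candidate sets, stoichiometry elements, ...) is refused:
#' run [mif_downgrade()] first.
#'
#' @param doc A [mif_document()].
#' @param path Optional output path; with a `.gz` suffix the stream is
#'   gzip-compressed.  When `NULL` the XML is returned as a string.
#' @param form `"compact"` (default) or `"extended"`.
#' @return The XML text, invisibly when written to `path`.
#' @export
write_mif <- function(doc, path = NULL, form = c("compact", "extended")) {
  if (!inherits(doc, "mif_document")) mif_abort("`doc` must be a <mif_document>")
  form <- match.arg(form)
  if (doc$level == "2.5") {
    used <- scan_30_constructs(doc)
    if (length(used) > 0L) {
      cats <- unique(vapply(used, function(u) u$category, character(1)))
      mif_abort(
        sprintf(paste0("document is at level 2.5 but uses 3.0-only ",
                       "constructs (%s); run mif_downgrade() first"),
                paste(cats, collapse = ", ")),
        class = "psimif_level"
      )
    }
  }
  ctx <- new.env(parent = emptyenv())
  ctx$form <- form
  ctx$level <- doc$level
  root_attrs <- if (doc$level == "3.0") {
    sprintf('xmlns="%s" level="3" version="0" minorVersion="0"', MIF300_NS)
  } else {
    sprintf('xmlns="%s" level="2" version="5" minorVersion="4"', MIF25_NS)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf("<entrySet %s>", root_attrs),
    unlist(lapply(doc$entries, function(e) w_entry("  ", e, ctx))),
    "</entrySet>"
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "wb")
    writeBin(charToRaw(txt), con)
    close(con)
  } else {
    writeBin(charToRaw(txt), path)
  }
  invisible(txt)
}

# serialize a single model object as an XML snippet (used by the 2.5
# downgrade to preserve 3.0 constructs inside attributes)
mif_snippet <- function(obj, tag = NULL) {
  lines <- if (inherits(obj, "mif_feature_range")) {
    w_feature_range("", obj, "3.0")
  } else if (inherits(obj, "mif_resulting_sequence")) {
    w_resulting_sequence("", obj)
  } else if (inherits(obj, "mif_cv")) {
    w_cv("", tag %||% "cvTerm", obj)
  } else if (inherits(obj, "mif_parameter")) {
    w_parameter("", obj)
  } else if (inherits(obj, "mif_variable_parameter")) {
    w_variable_parameter("", obj)
  } else if (inherits(obj, "mif_candidate_set")) {
    ctx <- new.env(parent = emptyenv())
    ctx$form <- "compact"
    ctx$level <- "3.0"
    w_candidate_set("", obj, ctx)
  } else if (inherits(obj, "mif_abstract_interaction")) {
    ctx <- new.env(parent = emptyenv())
    ctx$form <- "compact"
    ctx$level <- "3.0"
    w_abstract("", obj, ctx)
  } else if (inherits(obj, "mif_bibref")) {
    w_bibref("", obj)
  } else if (inherits(obj, "mif_attribute")) {
    w_attribute("", obj)
  } else {
    mif_abort(sprintf("cannot snippet a <%s>", class(obj)[1]))
  }
  paste(lines, collapse = "\n")
}
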