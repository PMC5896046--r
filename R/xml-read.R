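# Reading MIF documents with xml2.  Namespaces are stripped after level
# detection, so the parse functions work on plain element names for both
# levels and for embedded snippets.

xfirst <- function(node, name) {
  n <- xml2::xml_find_first(node, paste0("./", name))
  if (inherits(n, "xml_missing")) NULL else n
}
xall <- function(node, name) xml2::xml_find_all(node, paste0("./", name))
xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}
xattr_int <- function(node, name) {
  v <- xattr(node, name)
  if (is.null(v)) NULL else as.integer(v)
}
xtext <- function(node) xml2::xml_text(node)
xtext_of <- function(node, name) {
  n <- xfirst(node, name)
  if (is.null(n)) NULL else xtext(n)
}
xbool_of <- function(node, name, default = FALSE) {
  n <- xfirst(node, name)
  if (is.null(n)) return(default)
  tolower(xtext(n)) %in% c("true", "1")
}

p_names <- function(node) {
  if (is.null(node)) return(NULL)
  mif_names(short_label = xtext_of(node, "shortLabel"),
            full_name = xtext_of(node, "fullName"),
            aliases = vapply(xall(node, "alias"), xtext, character(1)))
}

p_dbref <- function(node) {
  mif_dbref(db = xattr(node, "db"), id = xattr(node, "id"),
            db_ac = xattr(node, "dbAc"), version = xattr(node, "version"),
            ref_type = xattr(node, "refType"),
            ref_type_ac = xattr(node, "refTypeAc"))
}

p_xref <- function(node) {
  if (is.null(node)) return(NULL)
  prim <- xfirst(node, "primaryRef")
  if (is.null(prim)) return(NULL)
  mif_xref(p_dbref(prim), lapply(xall(node, "secondaryRef"), p_dbref))
}

is_synth_dbref <- function(r, acc) {
  identical(r$db, "psi-mi") && identical(r$id, acc) &&
    identical(r$ref_type, "identity")
}

p_cv <- function(node) {
  if (is.null(node)) return(NULL)
  nm <- p_names(xfirst(node, "names"))
  x <- p_xref(xfirst(node, "xref"))
  acc <- NULL
  if (!is.null(x)) {
    if (identical(x$primary$db, "psi-mi") && is_mi_accession(x$primary$id)) {
      acc <- x$primary$id
    } else {
      for (s in x$secondary) {
        if (identical(s$db, "psi-mi") && is_mi_accession(s$id)) {
          acc <- s$id
          break
        }
      }
    }
    if (!is.null(acc)) {
      # undo writer-synthesized xrefs so the model round-trips
      if (is_synth_dbref(x$primary, acc) && length(x$secondary) == 0L) {
        x <- NULL
      } else {
        keep <- !vapply(x$secondary, is_synth_dbref, logical(1), acc = acc)
        x$secondary <- x$secondary[keep]
      }
    }
  }
  mif_cv(short_label = nm$short_label %||% NULL,
         full_name = nm$full_name %||% NULL,
         mi_accession = acc, xref = x)
}

p_attribute <- function(node) {
  mif_attribute(name = xattr(node, "name"), name_ac = xattr(node, "nameAc"),
                value = {
                  v <- xtext(node)
                  if (nzchar(v)) v else NULL
                })
}

p_attributes <- function(node) {
  if (is.null(node)) return(list())
  lapply(xall(node, "attribute"), p_attribute)
}

p_bibref <- function(node) {
  if (is.null(node)) return(NULL)
  mif_bibref(xref = p_xref(xfirst(node, "xref")),
             attributes = p_attributes(xfirst(node, "attributeList")))
}

p_organism <- function(node) {
  if (is.null(node)) return(NULL)
  mif_organism(ncbi_tax_id = xattr_int(node, "ncbiTaxId"),
               names = p_names(xfirst(node, "names")),
               cell_type = p_cv(xfirst(node, "cellType")),
               compartment = p_cv(xfirst(node, "compartment")),
               tissue = p_cv(xfirst(node, "tissue")))
}

p_parameter <- function(node) {
  fac <- xattr(node, "factor")
  unc <- xattr(node, "uncertainty")
  mif_parameter(
    term = xattr(node, "term"), term_ac = xattr(node, "termAc"),
    unit = xattr(node, "unit"), unit_ac = xattr(node, "unitAc"),
    base = xattr_int(node, "base") %||% 10L,
    exponent = xattr_int(node, "exponent") %||% 0L,
    factor = as.numeric(fac), factor_lexical = fac,
    uncertainty = if (is.null(unc)) NULL else as.numeric(unc),
    experiment_ref = {
      er <- xtext_of(node, "experimentRef")
      if (is.null(er)) NULL else as.integer(er)
    }
  )
}

p_parameters <- function(node) {
  if (is.null(node)) return(list())
  lapply(xall(node, "parameter"), p_parameter)
}

p_confidences <- function(node) {
  if (is.null(node)) return(list())
  lapply(xall(node, "confidence"), function(cn) {
    mif_confidence(unit = p_cv(xfirst(cn, "unit")),
                   value = xtext_of(cn, "value") %||% "")
  })
}

p_variable_parameter <- function(node) {
  vvl <- xfirst(node, "variableValueList")
  values <- if (is.null(vvl)) list() else {
    lapply(xall(vvl, "variableValue"), function(vn) {
      mif_variable_value(id = xattr_int(vn, "id"), value = xtext(vn),
                         order = xattr_int(vn, "order"))
    })
  }
  mif_variable_parameter(description = xtext_of(node, "description"),
                         unit = p_cv(xfirst(node, "unit")),
                         values = values)
}

p_experiment <- function(node) {
  hol <- xfirst(node, "hostOrganismList")
  vpl <- xfirst(node, "variableParameterList")
  mif_experiment(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    bibref = p_bibref(xfirst(node, "bibref")),
    xref = p_xref(xfirst(node, "xref")),
    host_organisms = if (is.null(hol)) list() else
      lapply(xall(hol, "hostOrganism"), p_organism),
    interaction_detection_method = p_cv(xfirst(node, "interactionDetectionMethod")),
    participant_identification_method =
      p_cv(xfirst(node, "participantIdentificationMethod")),
    feature_detection_method = p_cv(xfirst(node, "featureDetectionMethod")),
    variable_parameters = if (is.null(vpl)) list() else
      lapply(xall(vpl, "variableParameter"), p_variable_parameter),
    confidences = p_confidences(xfirst(node, "confidenceList")),
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

p_interactor <- function(node) {
  mif_interactor(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    xref = p_xref(xfirst(node, "xref")),
    interactor_type = p_cv(xfirst(node, "interactorType")),
    organism = p_organism(xfirst(node, "organism")),
    sequence = xtext_of(node, "sequence"),
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

p_position <- function(node, tag_exact, tag_interval) {
  ex <- xfirst(node, tag_exact)
  if (!is.null(ex)) return(mif_pos_exact(xattr_int(ex, "position")))
  iv <- xfirst(node, tag_interval)
  if (!is.null(iv)) {
    return(mif_pos_interval(xattr_int(iv, "begin"), xattr_int(iv, "end")))
  }
  mif_pos_unstated()
}

p_resulting_sequence <- function(node) {
  if (is.null(node)) return(NULL)
  orig <- xtext_of(node, "originalSequence")
  new <- xtext_of(node, "newSequence")
  x <- p_xref(xfirst(node, "xref"))
  # tolerate invalid emptiness at parse time; the validator reports it
  out <- try(mif_resulting_sequence(orig, new, x), silent = TRUE)
  if (inherits(out, "try-error")) {
    out <- structure(list(original = orig, new = new, xref = x),
                     class = "mif_resulting_sequence")
  }
  out
}

p_feature_range <- function(node) {
  mif_feature_range(
    begin_status = p_cv(xfirst(node, "startStatus")),
    begin = p_position(node, "begin", "beginInterval"),
    end_status = p_cv(xfirst(node, "endStatus")),
    end = p_position(node, "end", "endInterval"),
    is_link = xbool_of(node, "isLink"),
    resulting_sequence = p_resulting_sequence(xfirst(node, "resultingSequence"))
  )
}

p_feature <- function(node) {
  frl <- xfirst(node, "featureRangeList")
  mif_feature(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    xref = p_xref(xfirst(node, "xref")),
    feature_type = p_cv(xfirst(node, "featureType")),
    feature_role = p_cv(xfirst(node, "featureRole")),
    detection_methods = lapply(xall(node, "featureDetectionMethod"), p_cv),
    ranges = if (is.null(frl)) list() else
      lapply(xall(frl, "featureRange"), p_feature_range),
    parameters = p_parameters(xfirst(node, "parameterList")),
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

# entity helpers hoist inline definitions into the entry-level collector
hoist_interactor <- function(node, coll) {
  it <- p_interactor(node)
  key <- as.character(it$id)
  if (is.null(coll$interactors[[key]])) coll$interactors[[key]] <- it
  it$id
}

hoist_experiment <- function(node, coll) {
  ex <- p_experiment(node)
  key <- as.character(ex$id)
  if (is.null(coll$experiments[[key]])) coll$experiments[[key]] <- ex
  ex$id
}

p_candidate_set <- function(node, coll) {
  cands <- lapply(xall(node, "interactorCandidate"), function(cn) {
    inline <- xfirst(cn, "interactor")
    ref <- if (!is.null(inline)) {
      hoist_interactor(inline, coll)
    } else {
      as.integer(xtext_of(cn, "interactorRef"))
    }
    fl <- xfirst(cn, "featureList")
    mif_candidate(id = xattr_int(cn, "id"), interactor_ref = ref,
                  features = if (is.null(fl)) list() else
                    lapply(xall(fl, "feature"), p_feature))
  })
  mif_candidate_set(set_type = p_cv(xfirst(node, "moleculeSetType")),
                    candidates = cands)
}

p_participant <- function(node, coll) {
  entity <- {
    icl <- xfirst(node, "interactorCandidateList")
    inline <- xfirst(node, "interactor")
    iref <- xfirst(node, "interactorRef")
    aref <- xfirst(node, "interactionRef")
    if (!is.null(icl)) {
      mif_entity(candidate_set = p_candidate_set(icl, coll))
    } else if (!is.null(inline)) {
      mif_entity(interactor_ref = hoist_interactor(inline, coll))
    } else if (!is.null(iref)) {
      mif_entity(interactor_ref = as.integer(xtext(iref)))
    } else if (!is.null(aref)) {
      mif_entity(interaction_ref = as.integer(xtext(aref)))
    } else {
      mif_abort(sprintf("participant %s has no entity",
                        xattr(node, "id") %||% "?"),
                class = "psimif_parse")
    }
  }
  stoich <- {
    sm <- xfirst(node, "stoichiometry")
    sr <- xfirst(node, "stoichiometryRange")
    if (!is.null(sm)) {
      v <- xattr(sm, "value")
      mif_stoich_mean(as.numeric(v), lexical = v)
    } else if (!is.null(sr)) {
      mn <- xattr(sr, "minValue")
      mx <- xattr(sr, "maxValue")
      mif_stoich_range(as.numeric(mn), as.numeric(mx),
                       min_lexical = mn, max_lexical = mx)
    } else {
      mif_stoich_unstated()
    }
  }
  piml <- xfirst(node, "participantIdentificationMethodList")
  erl <- xfirst(node, "experimentalRoleList")
  epl <- xfirst(node, "experimentalPreparationList")
  fl <- xfirst(node, "featureList")
  hol <- xfirst(node, "hostOrganismList")
  mif_participant(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    xref = p_xref(xfirst(node, "xref")),
    entity = entity,
    identification_methods = if (is.null(piml)) list() else
      lapply(xall(piml, "participantIdentificationMethod"), p_cv),
    biological_role = p_cv(xfirst(node, "biologicalRole")),
    experimental_roles = if (is.null(erl)) list() else
      lapply(xall(erl, "experimentalRole"), p_cv),
    experimental_preparations = if (is.null(epl)) list() else
      lapply(xall(epl, "experimentalPreparation"), p_cv),
    features = if (is.null(fl)) list() else
      lapply(xall(fl, "feature"), p_feature),
    host_organisms = if (is.null(hol)) list() else
      lapply(xall(hol, "hostOrganism"), p_organism),
    confidences = p_confidences(xfirst(node, "confidenceList")),
    parameters = p_parameters(xfirst(node, "parameterList")),
    stoichiometry = stoich,
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

p_experiment_refs <- function(node, coll) {
  if (is.null(node)) return(integer(0))
  refs <- integer(0)
  for (ch in xml2::xml_children(node)) {
    nm <- xml2::xml_name(ch)
    if (nm == "experimentRef") {
      refs <- c(refs, as.integer(xtext(ch)))
    } else if (nm == "experimentDescription") {
      refs <- c(refs, hoist_experiment(ch, coll))
    }
  }
  refs
}

p_inferred <- function(node) {
  if (is.null(node)) return(list())
  lapply(xall(node, "inferredInteraction"), function(gn) {
    unlist(lapply(xall(gn, "participant"), function(pn) {
      pr <- xfirst(pn, "participantRef")
      fr <- xfirst(pn, "participantFeatureRef")
      if (!is.null(pr)) {
        list(list(kind = "participant", ref = as.integer(xtext(pr))))
      } else if (!is.null(fr)) {
        list(list(kind = "feature", ref = as.integer(xtext(fr))))
      } else {
        list()
      }
    }), recursive = FALSE)
  })
}

p_interaction <- function(node, coll) {
  pl <- xfirst(node, "participantList")
  mif_interaction(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    xref = p_xref(xfirst(node, "xref")),
    experiment_refs = p_experiment_refs(xfirst(node, "experimentList"), coll),
    participants = if (is.null(pl)) list() else
      lapply(xall(pl, "participant"), p_participant, coll = coll),
    inferred_interactions = p_inferred(xfirst(node, "inferredInteractionList")),
    interaction_types = lapply(xall(node, "interactionType"), p_cv),
    negative = xbool_of(node, "negative"),
    intra_molecular = xbool_of(node, "intraMolecular"),
    confidences = p_confidences(xfirst(node, "confidenceList")),
    parameters = p_parameters(xfirst(node, "parameterList")),
    condition_sets = lapply(xall(node, "variableValueRefList"), function(sn) {
      vapply(xall(sn, "variableValueRef"),
             function(rn) as.integer(xtext(rn)), integer(1))
    }),
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

p_coop_effect <- function(node) {
  kind <- xml2::xml_name(node)
  evl <- xfirst(node, "cooperativeEffectEvidenceList")
  evidence <- if (is.null(evl)) list() else {
    lapply(xall(evl, "cooperativeEffectEvidence"), function(en) {
      eml <- xfirst(en, "evidenceMethodList")
      list(bibref = p_bibref(xfirst(en, "bibref")),
           methods = if (is.null(eml)) list() else
             lapply(xall(eml, "evidenceMethod"), p_cv))
    })
  }
  ail <- xfirst(node, "affectedInteractionList")
  affected <- if (is.null(ail)) integer(0) else {
    vapply(xall(ail, "affectedInteractionRef"),
           function(rn) as.integer(xtext(rn)), integer(1))
  }
  outcome <- p_cv(xfirst(node, "cooperativeEffectOutcome"))
  response <- p_cv(xfirst(node, "cooperativeEffectResponse"))
  if (kind == "preassembly") {
    return(mif_preassembly(affected, outcome, response, evidence))
  }
  mer <- xfirst(node, "moleculeEffectorRef")
  fer <- xfirst(node, "featureModificationEffectorRef")
  effector <- if (!is.null(mer)) {
    list(kind = "molecule", ref = as.integer(xtext(mer)))
  } else {
    list(kind = "feature_modification", ref = as.integer(xtext(fer)))
  }
  mif_allostery(
    affected_refs = affected, outcome = outcome,
    allosteric_molecule_ref = as.integer(xtext_of(node, "allostericMoleculeRef")),
    effector = effector, response = response, evidence = evidence,
    allostery_type = p_cv(xfirst(node, "allosteryType")),
    allosteric_mechanism = p_cv(xfirst(node, "allostericMechanism"))
  )
}

p_abstract <- function(node, coll) {
  pl <- xfirst(node, "participantList")
  bfl <- xfirst(node, "bindingFeatureList")
  cel <- xfirst(node, "cooperativeEffectList")
  out <- mif_abstract_interaction(
    id = xattr_int(node, "id"),
    names = p_names(xfirst(node, "names")),
    xref = p_xref(xfirst(node, "xref")),
    interactor_type = p_cv(xfirst(node, "interactorType")),
    interaction_type = p_cv(xfirst(node, "interactionType")),
    organism = p_organism(xfirst(node, "organism")),
    participants = if (is.null(pl)) list() else
      lapply(xall(pl, "participant"), p_participant, coll = coll),
    binding_features = if (is.null(bfl)) list() else
      lapply(xall(bfl, "bindingFeatures"), function(bn) {
        vapply(xall(bn, "participantFeatureRef"),
               function(rn) as.integer(xtext(rn)), integer(1))
      }),
    cooperative_effects = if (is.null(cel)) list() else
      lapply(xml2::xml_children(cel), p_coop_effect),
    evidence_type = p_cv(xfirst(node, "evidenceType")),
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
  # an experimentList here is invalid at 3.0; keep refs so the validator
  # can report ABSTRACT_HAS_EXPERIMENT
  out$experiment_refs <- p_experiment_refs(xfirst(node, "experimentList"), coll)
  out
}

p_source <- function(node) {
  if (is.null(node)) return(NULL)
  mif_source(names = p_names(xfirst(node, "names")),
             xref = p_xref(xfirst(node, "xref")),
             bibref = p_bibref(xfirst(node, "bibref")),
             attributes = p_attributes(xfirst(node, "attributeList")),
             release_date = xattr(node, "releaseDate"))
}

p_entry <- function(node) {
  coll <- new.env(parent = emptyenv())
  coll$experiments <- list()
  coll$interactors <- list()
  exl <- xfirst(node, "experimentList")
  if (!is.null(exl)) {
    for (en in xall(exl, "experimentDescription")) hoist_experiment(en, coll)
  }
  inl <- xfirst(node, "interactorList")
  if (!is.null(inl)) {
    for (itn in xall(inl, "interactor")) hoist_interactor(itn, coll)
  }
  ial <- xfirst(node, "interactionList")
  interactions <- list()
  if (!is.null(ial)) {
    for (ian in xml2::xml_children(ial)) {
      nm <- xml2::xml_name(ian)
      if (nm == "interaction") {
        interactions[[length(interactions) + 1L]] <- p_interaction(ian, coll)
      } else if (nm == "abstractInteraction") {
        interactions[[length(interactions) + 1L]] <- p_abstract(ian, coll)
      }
    }
  }
  avl <- xfirst(node, "availabilityList")
  mif_entry(
    source = p_source(xfirst(node, "source")),
    availabilities = if (is.null(avl)) list() else
      lapply(xall(avl, "availability"), function(an) {
        mif_availability(xattr_int(an, "id"), xtext(an))
      }),
    experiments = unname(coll$experiments),
    interactors = unname(coll$interactors),
    interactions = interactions,
    attributes = p_attributes(xfirst(node, "attributeList"))
  )
}

# ---- stream handling --------------------------------------------------------

mif_source_text <- function(x) {
  if (is.raw(x)) {
    bytes <- x
  } else if (is.character(x) && length(x) == 1L && grepl("^\\s*<", x)) {
    return(x)
  } else if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      mif_abort(sprintf("file not found: %s", x), class = "psimif_io")
    }
    bytes <- readBin(x, "raw", n = file.size(x))
  } else {
    mif_abort("input must be a path, an XML string or a raw vector",
              class = "psimif_io")
  }
  if (length(bytes) >= 2L && bytes[1] == as.raw(0x1f) && bytes[2] == as.raw(0x8b)) {
    bytes <- memDecompress(bytes, type = "gzip")
  }
  rawToChar(bytes)
}

#' Detect the format level of a MIF stream
#'
#' Inspects the root element's namespace and `level`/`version` attributes.
#'
#' @param x Path, XML string or raw vector (optionally gzip-compressed).
#' @return `"2.5"` or `"3.0"`.
#' @export
detect_level <- function(x) {
  txt <- mif_source_text(x)
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e) {
                    mif_abort(sprintf("malformed XML: %s", conditionMessage(e)),
                              class = "psimif_parse")
                  })
  root <- xml2::xml_root(doc)
  uris <- tryCatch(as.character(unlist(xml2::xml_ns(doc))),
                   error = function(e) character(0))
  uris <- setdiff(uris, c("http://www.w3.org/2001/XMLSchema-instance",
                          "http://www.w3.org/XML/1998/namespace"))
  if (MIF300_NS %in% uris) return("3.0")
  if (MIF25_NS %in% uris) return("2.5")
  lv <- xml2::xml_attr(root, "level")
  if (!is.na(lv)) {
    if (lv == "3") return("3.0")
    if (lv == "2") return("2.5")
  }
  if (length(uris) > 0L) {
    mif_abort(sprintf("unrecognized document namespace: %s", uris[1]),
              class = "psimif_namespace", namespace = uris[1])
  }
  mif_abort("cannot determine MIF level (no namespace or level attribute)",
            class = "psimif_namespace")
}

new_finding <- function(code, severity, path, message) {
  structure(list(code = code, severity = severity, path = path,
                 message = message),
            class = "mif_finding")
}

#' Read a PSI-MI XML document
#'
#' Parses a level 2.5 or 3.0 document in either the compact or the extended
#' form into one in-memory object graph: inline experiment and interactor
#' definitions are hoisted to the entry lists and referenced by id, so a
#' compact and an extended serialization of the same content read to
#' semantically equal documents.
#'
#' @param x Path, XML string or raw vector; gzip input is sniffed from the
#'   magic bytes.
#' @param strict If `TRUE` any unresolved id reference is fatal (no
#'   document is returned); otherwise dangling references are reported as
#'   findings and dropped from reference lists.
#' @param keep_dangling Keep dangling references in the non-strict document
#'   instead of dropping them (so a later [mif_validate()] can flag them);
#'   default `FALSE`.
#' @return An object of class `mif_read_result`: `document` (a
#'   [mif_document()], or `NULL` on fatal findings), `findings` (list of
#'   syntactic findings) and `level_detected`.
#' @export
read_mif <- function(x, strict = FALSE, keep_dangling = FALSE) {
  level <- detect_level(x)
  txt <- mif_source_text(x)
  xdoc <- xml2::read_xml(txt)
  xml2::xml_ns_strip(xdoc)
  root <- xml2::xml_root(xdoc)
  entries <- lapply(xall(root, "entry"), p_entry)
  doc <- mif_document(entries, level = level)
  findings <- list()
  dangling <- document_dangling_refs(doc)
  for (d in dangling) {
    findings[[length(findings) + 1L]] <- new_finding(
      "DANGLING_REF", if (strict) "error" else "warning", d$path,
      sprintf("reference to undefined id %d", d$id))
  }
  if (strict && length(dangling) > 0L) {
    return(structure(list(document = NULL, findings = findings,
                          level_detected = level),
                     class = "mif_read_result"))
  }
  if (length(dangling) > 0L && !keep_dangling) doc <- drop_dangling_refs(doc)
  structure(list(document = doc, findings = findings,
                 level_detected = level),
            class = "mif_read_result")
}

# drop dangling ids from droppable reference lists (entity references are
# kept: removing them would destroy the participant)
drop_dangling_refs <- function(doc) {
  doc$entries <- lapply(doc$entries, function(entry) {
    defined <- entry_defined_ids(entry)
    keep <- function(v) v[v %in% defined]
    entry$interactions <- lapply(entry$interactions, function(ia) {
      ia$experiment_refs <- keep(ia$experiment_refs)
      if (inherits(ia, "mif_interaction")) {
        ia$condition_sets <- Filter(length, lapply(ia$condition_sets, keep))
        ia$inferred_interactions <- Filter(length,
          lapply(ia$inferred_interactions, function(g) {
            Filter(function(item) item$ref %in% defined, g)
          }))
      } else {
        ia$binding_features <- Filter(length,
                                      lapply(ia$binding_features, keep))
      }
      ia
    })
    entry
  })
  doc
}

# parse a single-element XML snippet produced by mif_snippet()
mif_parse_snippet <- function(txt) {
  node <- xml2::read_xml(txt)
  xml2::xml_ns_strip(node)
  nm <- xml2::xml_name(node)
  coll <- new.env(parent = emptyenv())
  coll$experiments <- list()
  coll$interactors <- list()
  switch(nm,
    featureRange = p_feature_range(node),
    resultingSequence = p_resulting_sequence(node),
    parameter = p_parameter(node),
    variableParameter = p_variable_parameter(node),
    interactorCandidateList = p_candidate_set(node, coll),
    abstractInteraction = p_abstract(node, coll),
    bibref = p_bibref(node),
    attribute = p_attribute(node),
    p_cv(node)  # any CV-shaped element
  )
}
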