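# Hand-written structural conformance check for MIF documents.
#
# A rule table drives a recursive walk over the element tree: allowed and
# required children, at-most-once children, exclusive choices, required
# attributes, and level-specific restrictions (2.5 positions are unsigned,
# a 2.5 feature has a single detection method, a 2.5 bibref is an
# exclusive choice, and 3.0-only elements are forbidden at 2.5).

CV_ELEMENTS <- c("interactionDetectionMethod", "participantIdentificationMethod",
                 "featureDetectionMethod", "interactorType", "moleculeSetType",
                 "biologicalRole", "experimentalRole", "experimentalPreparation",
                 "featureType", "featureRole", "startStatus", "endStatus",
                 "interactionType", "unit", "evidenceMethod",
                 "cooperativeEffectOutcome", "cooperativeEffectResponse",
                 "allosteryType", "allostericMechanism", "evidenceType",
                 "cellType", "compartment", "tissue")

MIF30_ONLY_ELEMENTS <- c("resultingSequence", "featureRole",
                         "variableParameterList", "variableValueRefList",
                         "abstractInteraction", "interactorCandidateList",
                         "stoichiometry", "stoichiometryRange")

structure_rules <- function() {
  cv_rule <- list(children = c("names", "xref"))
  text_rule <- list(children = character(0))
  rules <- list(
    entrySet = list(children = "entry", required = "entry"),
    entry = list(children = c("source", "availabilityList", "experimentList",
                              "interactorList", "interactionList",
                              "attributeList"),
                 once = c("source", "availabilityList", "experimentList",
                          "interactorList", "interactionList",
                          "attributeList")),
    source = list(children = c("names", "xref", "bibref", "attributeList")),
    availabilityList = list(children = "availability",
                            required = "availability"),
    availability = list(children = character(0), attrs_required = "id"),
    experimentList = list(children = c("experimentDescription",
                                       "experimentRef")),
    experimentDescription = list(
      children = c("names", "bibref", "xref", "hostOrganismList",
                   "interactionDetectionMethod",
                   "participantIdentificationMethod",
                   "featureDetectionMethod", "variableParameterList",
                   "confidenceList", "attributeList"),
      required = c("bibref", "interactionDetectionMethod"),
      once = c("names", "bibref", "xref", "interactionDetectionMethod",
               "featureDetectionMethod", "variableParameterList"),
      attrs_required = "id"),
    bibref = list(children = c("xref", "attributeList"),
                  once = c("xref", "attributeList")),
    names = list(children = c("shortLabel", "fullName", "alias"),
                 once = c("shortLabel", "fullName")),
    shortLabel = text_rule, fullName = text_rule, alias = text_rule,
    xref = list(children = c("primaryRef", "secondaryRef"),
                required = "primaryRef", once = "primaryRef"),
    primaryRef = list(children = character(0),
                      attrs_required = c("db", "id")),
    secondaryRef = list(children = character(0),
                        attrs_required = c("db", "id")),
    attributeList = list(children = "attribute"),
    attribute = list(children = character(0), attrs_required = "name"),
    hostOrganismList = list(children = "hostOrganism",
                            required = "hostOrganism"),
    hostOrganism = list(children = c("names", "cellType", "compartment",
                                     "tissue"),
                        attrs_required = "ncbiTaxId"),
    organism = list(children = c("names", "cellType", "compartment",
                                 "tissue"),
                    attrs_required = "ncbiTaxId"),
    variableParameterList = list(children = "variableParameter",
                                 required = "variableParameter"),
    variableParameter = list(children = c("description", "unit",
                                          "variableValueList"),
                             required = c("description", "variableValueList"),
                             once = c("description", "unit",
                                      "variableValueList")),
    description = text_rule,
    variableValueList = list(children = "variableValue",
                             required = "variableValue"),
    variableValue = list(children = character(0), attrs_required = "id"),
    confidenceList = list(children = "confidence", required = "confidence"),
    confidence = list(children = c("unit", "value"),
                      required = c("unit", "value")),
    value = text_rule,
    interactorList = list(children = "interactor"),
    interactor = list(children = c("names", "xref", "interactorType",
                                   "organism", "sequence", "attributeList"),
                      required = "interactorType",
                      attrs_required = "id"),
    sequence = text_rule,
    interactionList = list(children = c("interaction",
                                        "abstractInteraction")),
    interaction = list(
      children = c("names", "xref", "experimentList", "participantList",
                   "inferredInteractionList", "interactionType", "negative",
                   "intraMolecular", "confidenceList", "parameterList",
                   "variableValueRefList", "attributeList"),
      once = c("names", "xref", "experimentList", "participantList",
               "negative", "intraMolecular", "parameterList"),
      attrs_required = "id"),
    experimentRef = text_rule,
    participantList = list(children = "participant",
                           required = "participant"),
    participant = list(
      children = c("names", "xref", "interactor", "interactorRef",
                   "interactionRef", "interactorCandidateList",
                   "participantIdentificationMethodList", "biologicalRole",
                   "experimentalRoleList", "experimentalPreparationList",
                   "featureList", "hostOrganismList", "confidenceList",
                   "parameterList", "stoichiometry", "stoichiometryRange",
                   "attributeList"),
      choices = list(list(members = c("interactor", "interactorRef",
                                      "interactionRef",
                                      "interactorCandidateList"),
                          min = 1L, max = 1L),
                     list(members = c("stoichiometry", "stoichiometryRange"),
                          min = 0L, max = 1L)),
      attrs_required = "id"),
    interactorRef = text_rule, interactionRef = text_rule,
    interactorCandidateList = list(
      children = c("moleculeSetType", "interactorCandidate"),
      required = c("moleculeSetType", "interactorCandidate"),
      once = "moleculeSetType"),
    interactorCandidate = list(
      children = c("interactor", "interactorRef", "featureList"),
      choices = list(list(members = c("interactor", "interactorRef"),
                          min = 1L, max = 1L)),
      attrs_required = "id"),
    participantIdentificationMethodList =
      list(children = "participantIdentificationMethod",
           required = "participantIdentificationMethod"),
    experimentalRoleList = list(children = "experimentalRole",
                                required = "experimentalRole"),
    experimentalPreparationList = list(children = "experimentalPreparation",
                                       required = "experimentalPreparation"),
    featureList = list(children = "feature", required = "feature"),
    feature = list(
      children = c("names", "xref", "featureType", "featureRole",
                   "featureDetectionMethod", "featureRangeList",
                   "parameterList", "attributeList"),
      required = "featureRangeList",
      once = c("names", "xref", "featureType", "featureRole",
               "featureRangeList", "parameterList"),
      attrs_required = "id"),
    featureRangeList = list(children = "featureRange",
                            required = "featureRange"),
    featureRange = list(
      children = c("startStatus", "begin", "beginInterval", "endStatus",
                   "end", "endInterval", "isLink", "resultingSequence"),
      required = c("startStatus", "endStatus"),
      choices = list(list(members = c("begin", "beginInterval"),
                          min = 0L, max = 1L),
                     list(members = c("end", "endInterval"),
                          min = 0L, max = 1L))),
    begin = list(children = character(0), attrs_required = "position"),
    end = list(children = character(0), attrs_required = "position"),
    beginInterval = list(children = character(0),
                         attrs_required = c("begin", "end")),
    endInterval = list(children = character(0),
                       attrs_required = c("begin", "end")),
    isLink = text_rule,
    resultingSequence = list(children = c("originalSequence", "newSequence",
                                          "xref")),
    originalSequence = text_rule, newSequence = text_rule,
    parameterList = list(children = "parameter", required = "parameter"),
    parameter = list(children = "experimentRef",
                     attrs_required = c("term", "factor")),
    inferredInteractionList = list(children = "inferredInteraction",
                                   required = "inferredInteraction"),
    inferredInteraction = list(children = "participant",
                               required = "participant"),
    "inferredInteraction>participant" = list(
      children = c("participantRef", "participantFeatureRef"),
      choices = list(list(members = c("participantRef",
                                      "participantFeatureRef"),
                          min = 1L, max = 1L))),
    participantRef = text_rule, participantFeatureRef = text_rule,
    negative = text_rule, intraMolecular = text_rule,
    stoichiometry = list(children = character(0), attrs_required = "value"),
    stoichiometryRange = list(children = character(0),
                              attrs_required = c("minValue", "maxValue")),
    variableValueRefList = list(children = "variableValueRef",
                                required = "variableValueRef"),
    variableValueRef = text_rule,
    abstractInteraction = list(
      children = c("names", "xref", "interactorType", "interactionType",
                   "organism", "participantList", "bindingFeatureList",
                   "cooperativeEffectList", "evidenceType", "attributeList"),
      attrs_required = "id"),
    bindingFeatureList = list(children = "bindingFeatures",
                              required = "bindingFeatures"),
    bindingFeatures = list(children = "participantFeatureRef",
                           required = "participantFeatureRef"),
    cooperativeEffectList = list(children = c("allostery", "preassembly"),
                                 required = character(0)),
    allostery = list(
      children = c("cooperativeEffectEvidenceList", "affectedInteractionList",
                   "cooperativeEffectOutcome", "cooperativeEffectResponse",
                   "allostericMoleculeRef", "moleculeEffectorRef",
                   "featureModificationEffectorRef", "allosteryType",
                   "allostericMechanism"),
      required = c("affectedInteractionList", "cooperativeEffectOutcome",
                   "allostericMoleculeRef"),
      choices = list(list(members = c("moleculeEffectorRef",
                                      "featureModificationEffectorRef"),
                          min = 1L, max = 1L))),
    preassembly = list(
      children = c("cooperativeEffectEvidenceList", "affectedInteractionList",
                   "cooperativeEffectOutcome", "cooperativeEffectResponse"),
      required = c("affectedInteractionList", "cooperativeEffectOutcome")),
    cooperativeEffectEvidenceList = list(
      children = "cooperativeEffectEvidence",
      required = "cooperativeEffectEvidence"),
    cooperativeEffectEvidence = list(children = c("bibref",
                                                  "evidenceMethodList")),
    evidenceMethodList = list(children = "evidenceMethod",
                              required = "evidenceMethod"),
    affectedInteractionList = list(children = "affectedInteractionRef",
                                   required = "affectedInteractionRef"),
    affectedInteractionRef = text_rule, allostericMoleculeRef = text_rule,
    moleculeEffectorRef = text_rule,
    featureModificationEffectorRef = text_rule
  )
  for (cv in CV_ELEMENTS) {
    if (is.null(rules[[cv]])) rules[[cv]] <- cv_rule
  }
  rules
}

.rules_cache <- new.env(parent = emptyenv())

get_structure_rules <- function() {
  if (is.null(.rules_cache$rules)) .rules_cache$rules <- structure_rules()
  .rules_cache$rules
}

check_node <- function(node, parent_name, path, level, rules, out) {
  name <- xml2::xml_name(node)
  key <- paste0(parent_name, ">", name)
  rule <- rules[[key]] %||% rules[[name]]
  add <- function(msg) out$items <- c(out$items, sprintf("%s: %s", path, msg))
  if (level == "2.5" && name %in% MIF30_ONLY_ELEMENTS) {
    add(sprintf("element <%s> is not allowed at level 2.5", name))
    return(invisible(NULL))
  }
  if (is.null(rule)) {
    add(sprintf("unknown element <%s>", name))
    return(invisible(NULL))
  }
  for (a in rule$attrs_required) {
    if (is.na(xml2::xml_attr(node, a))) {
      add(sprintf("missing required attribute '%s' on <%s>", a, name))
    }
  }
  kids <- xml2::xml_children(node)
  kid_names <- vapply(kids, xml2::xml_name, character(1))
  for (kn in setdiff(unique(kid_names), rule$children)) {
    add(sprintf("<%s> is not an allowed child of <%s>", kn, name))
  }
  for (req in rule$required) {
    if (!req %in% kid_names) {
      add(sprintf("<%s> requires a <%s> child", name, req))
    }
  }
  for (on in rule$once) {
    if (sum(kid_names == on) > 1L) {
      add(sprintf("<%s> allows at most one <%s> child", name, on))
    }
  }
  for (ch in rule$choices) {
    n <- sum(kid_names %in% ch$members)
    if (n < ch$min || n > ch$max) {
      add(sprintf("<%s> requires between %d and %d of {%s}", name,
                  ch$min, ch$max, paste(ch$members, collapse = ", ")))
    }
  }
  # level-specific content rules
  if (level == "2.5") {
    if (name == "feature" && sum(kid_names == "featureDetectionMethod") > 1L) {
      add("a 2.5 feature allows a single featureDetectionMethod")
    }
    if (name == "feature" && "parameterList" %in% kid_names) {
      add("feature-level parameters are not allowed at level 2.5")
    }
    if (name == "bibref" &&
        all(c("xref", "attributeList") %in% kid_names)) {
      add("a 2.5 bibref is a choice between xref and attributeList")
    }
    if (name %in% c("begin", "end")) {
      if (isTRUE(as.numeric(xml2::xml_attr(node, "position")) < 0)) {
        add("2.5 positions are unsigned")
      }
    }
    if (name %in% c("beginInterval", "endInterval")) {
      for (a in c("begin", "end")) {
        if (isTRUE(as.numeric(xml2::xml_attr(node, a)) < 0)) {
          add("2.5 interval bounds are unsigned")
        }
      }
    }
  } else {
    if (name == "bibref" && !any(c("xref", "attributeList") %in% kid_names)) {
      add("a bibref needs an xref or an attributeList")
    }
  }
  idx <- stats::setNames(rep(0L, length(unique(kid_names))), unique(kid_names))
  for (i in seq_along(kids)) {
    kn <- kid_names[i]
    idx[kn] <- idx[kn] + 1L
    check_node(kids[[i]], name, sprintf("%s/%s[%d]", path, kn, idx[kn]),
               level, rules, out)
  }
  invisible(NULL)
}

#' Structurally validate a MIF stream against its level
#'
#' Walks the element tree against a rule table encoding the document
#' grammar at each level: allowed/required children, exclusive choices,
#' required attributes, and level restrictions (level 2.5 forbids the
#' 3.0-only elements, restricts positions to unsigned values, a feature to
#' one detection method and a bibref to an exclusive choice).
#'
#' @param x Path, XML string or raw vector.
#' @param level `"2.5"`, `"3.0"` or `NULL` (auto-detected).
#' @return Character vector of violations; empty when conformant.
#' @export
mif_check_structure <- function(x, level = NULL) {
  level <- level %||% detect_level(x)
  txt <- mif_source_text(x)
  xdoc <- xml2::read_xml(txt)
  xml2::xml_ns_strip(xdoc)
  root <- xml2::xml_root(xdoc)
  out <- new.env(parent = emptyenv())
  out$items <- character(0)
  if (xml2::xml_name(root) != "entrySet") {
    out$items <- sprintf("/: root element is <%s>, expected <entrySet>",
                         xml2::xml_name(root))
    return(out$items)
  }
  check_node(root, "", "/entrySet", level, get_structure_rules(), out)
  out$items
}
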