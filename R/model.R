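#' Controlled-vocabulary term
#'
#' A reference to a term of the PSI-MI controlled vocabulary (or any other
#' CV).  At least one of `short_label` and `mi_accession` must be given; the
#' accession, when present, must match `MI:` followed by four digits.
#'
#' @param short_label Short human-readable label (e.g. `"protein"`).
#' @param full_name Optional full name.
#' @param mi_accession Optional accession of the form `MI:0326`.
#' @param xref Optional [mif_xref()] carrying additional cross-references.
#' @return An object of class `mif_cv`.
#' @export
#' @examples
#' mif_cv("protein", mi_accession = "MI:0326")
mif_cv <- function(short_label = NULL, full_name = NULL,
                   mi_accession = NULL, xref = NULL) {
  chk_string(short_label, "short_label", allow_null = TRUE)
  chk_string(full_name, "full_name", allow_null = TRUE)
  if (is.null(short_label) && is.null(mi_accession)) {
    mif_abort("a CV term needs a short_label or an mi_accession")
  }
  if (!is.null(mi_accession) && !is_mi_accession(mi_accession)) {
    mif_abort(sprintf("mi_accession '%s' does not match MI: + 4 digits",
                      mi_accession))
  }
  if (!is.null(xref) && !inherits(xref, "mif_xref")) {
    mif_abort("`xref` must be a <mif_xref>")
  }
  structure(list(short_label = short_label, full_name = full_name,
                 mi_accession = mi_accession, xref = xref),
            class = "mif_cv")
}

#' Database cross-reference
#'
#' @param db Database name (non-empty).
#' @param id Accession within the database (non-empty).
#' @param db_ac,version,ref_type,ref_type_ac Optional qualifiers.
#' @return An object of class `mif_dbref`.
#' @export
mif_dbref <- function(db, id, db_ac = NULL, version = NULL,
                      ref_type = NULL, ref_type_ac = NULL) {
  chk_string(db, "db")
  chk_string(id, "id")
  chk_string(db_ac, "db_ac", allow_null = TRUE)
  chk_string(version, "version", allow_null = TRUE)
  chk_string(ref_type, "ref_type", allow_null = TRUE)
  chk_string(ref_type_ac, "ref_type_ac", allow_null = TRUE)
  structure(list(db = db, db_ac = db_ac, id = id, version = version,
                 ref_type = ref_type, ref_type_ac = ref_type_ac),
            class = "mif_dbref")
}

#' Cross-reference block (primary + secondary references)
#'
#' @param primary A [mif_dbref()]; always required.
#' @param secondary List of additional [mif_dbref()] objects.
#' @return An object of class `mif_xref`.
#' @export
mif_xref <- function(primary, secondary = list()) {
  if (!inherits(primary, "mif_dbref")) {
    mif_abort("`primary` must be a <mif_dbref>")
  }
  secondary <- chk_list_of(secondary, "mif_dbref", "secondary")
  structure(list(primary = primary, secondary = secondary),
            class = "mif_xref")
}

#' Free-text annotation attribute
#'
#' @param name Attribute topic name (non-empty).
#' @param value Optional text value.
#' @param name_ac Optional accession for the topic.
#' @return An object of class `mif_attribute`.
#' @export
mif_attribute <- function(name, value = NULL, name_ac = NULL) {
  chk_string(name, "name")
  chk_string(value, "value", allow_null = TRUE, allow_empty = TRUE)
  chk_string(name_ac, "name_ac", allow_null = TRUE)
  structure(list(name = name, name_ac = name_ac, value = value),
            class = "mif_attribute")
}

#' Bibliographic reference
#'
#' At level 3.0 a publication may be described both by a cross-reference
#' (e.g. a PubMed identifier) and by free-text attributes (title, authors,
#' date) inside the same `bibref`; at least one of the two must be present.
#'
#' @param xref Optional [mif_xref()].
#' @param attributes List of [mif_attribute()] objects.
#' @return An object of class `mif_bibref`.
#' @export
mif_bibref <- function(xref = NULL, attributes = list()) {
  if (!is.null(xref) && !inherits(xref, "mif_xref")) {
    mif_abort("`xref` must be a <mif_xref>")
  }
  attributes <- chk_list_of(attributes, "mif_attribute", "attributes")
  if (is.null(xref) && length(attributes) == 0L) {
    mif_abort("a bibref needs an xref or at least one attribute")
  }
  structure(list(xref = xref, attributes = attributes),
            class = "mif_bibref")
}

#' Names block (short label / full name / aliases)
#' @param short_label,full_name Optional strings.
#' @param aliases Character vector of alias strings.
#' @return An object of class `mif_names`.
#' @export
mif_names <- function(short_label = NULL, full_name = NULL,
                      aliases = character()) {
  chk_string(short_label, "short_label", allow_null = TRUE)
  chk_string(full_name, "full_name", allow_null = TRUE)
  structure(list(short_label = short_label, full_name = full_name,
                 aliases = as.character(aliases)),
            class = "mif_names")
}

#' Host or source organism
#'
#' `ncbi_tax_id` follows NCBI taxonomy; negative sentinel values (-1
#' "in vitro", -2 "chemical synthesis", ...) are permitted, zero is not.
#'
#' @param ncbi_tax_id Integer taxon identifier, non-zero.
#' @param names Optional [mif_names()].
#' @param cell_type,compartment,tissue Optional open [mif_cv()] terms.
#' @return An object of class `mif_organism`.
#' @export
mif_organism <- function(ncbi_tax_id, names = NULL, cell_type = NULL,
                         compartment = NULL, tissue = NULL) {
  ncbi_tax_id <- chk_id(ncbi_tax_id, "ncbi_tax_id")
  if (ncbi_tax_id == 0L) mif_abort("ncbi_tax_id must not be 0")
  for (f in list(cell_type, compartment, tissue)) {
    if (!is.null(f) && !inherits(f, "mif_cv")) {
      mif_abort("cell_type/compartment/tissue must be <mif_cv>")
    }
  }
  structure(list(ncbi_tax_id = ncbi_tax_id, names = names,
                 cell_type = cell_type, compartment = compartment,
                 tissue = tissue),
            class = "mif_organism")
}

#' Numeric parameter (kinetic / affinity constant)
#'
#' Represents a measured quantity as `factor * base ^ exponent`, e.g. a
#' dissociation constant Kd = 2.5e-8 M as factor 2.5, base 10, exponent -8.
#' The lexical form of `factor` is retained so that a value round-trips
#' byte-identically through serialization.
#'
#' @param term Name of the measured quantity (e.g. `"kd"`); required.
#' @param factor Decimal mantissa; must be finite.
#' @param base Integer base, default 10, must be >= 2.
#' @param exponent Integer exponent, default 0.
#' @param term_ac,unit,unit_ac Optional qualifiers.
#' @param uncertainty Optional decimal uncertainty.
#' @param experiment_ref Optional id of the experiment the value came from.
#' @param factor_lexical Optional exact string form of `factor`.
#' @return An object of class `mif_parameter`.
#' @export
mif_parameter <- function(term, factor, base = 10L, exponent = 0L,
                          term_ac = NULL, unit = NULL, unit_ac = NULL,
                          uncertainty = NULL, experiment_ref = NULL,
                          factor_lexical = NULL) {
  chk_string(term, "term")
  factor <- chk_num(factor, "factor")
  if (!is.finite(factor)) mif_abort("parameter factor must be finite")
  base <- chk_id(base, "base")
  if (base < 2L) mif_abort("parameter base must be >= 2")
  exponent <- chk_id(exponent, "exponent")
  chk_string(term_ac, "term_ac", allow_null = TRUE)
  chk_string(unit, "unit", allow_null = TRUE)
  chk_string(unit_ac, "unit_ac", allow_null = TRUE)
  uncertainty <- chk_num(uncertainty, "uncertainty", allow_null = TRUE)
  experiment_ref <- chk_id(experiment_ref, "experiment_ref", allow_null = TRUE)
  chk_string(factor_lexical, "factor_lexical", allow_null = TRUE)
  structure(list(term = term, term_ac = term_ac, unit = unit,
                 unit_ac = unit_ac, base = base, exponent = exponent,
                 factor = factor, factor_lexical = factor_lexical,
                 uncertainty = uncertainty, experiment_ref = experiment_ref),
            class = "mif_parameter")
}

#' Variable experimental condition value
#'
#' One value of a variable parameter (e.g. `"4"` hours post-infection).
#' `order` positions the value within its list (0-based or 1-based at the
#' curator's discretion, must be >= 0 when given).
#'
#' @param id Entry-unique integer id (shared id namespace).
#' @param value Text value.
#' @param order Optional non-negative integer position.
#' @return An object of class `mif_variable_value`.
#' @export
mif_variable_value <- function(id, value, order = NULL) {
  id <- chk_id(id, "id")
  chk_string(value, "value")
  order <- chk_id(order, "order", allow_null = TRUE)
  structure(list(id = id, value = value, order = order),
            class = "mif_variable_value")
}

#' Variable experimental parameter (dynamic interactions)
#'
#' Describes one experimental condition that varies within an experiment —
#' e.g. agonist concentration or hours post-infection — together with the
#' list of values it took.
#'
#' @param description Required non-empty description of the condition.
#' @param values Non-empty list of [mif_variable_value()] objects.
#' @param unit Optional [mif_cv()] unit.
#' @return An object of class `mif_variable_parameter`.
#' @export
mif_variable_parameter <- function(description, values, unit = NULL) {
  chk_string(description, "description")
  values <- chk_list_of(values, "mif_variable_value", "values")
  if (length(values) == 0L) {
    mif_abort("a variable parameter needs at least one value")
  }
  if (!is.null(unit) && !inherits(unit, "mif_cv")) {
    mif_abort("`unit` must be a <mif_cv>")
  }
  structure(list(description = description, unit = unit, values = values),
            class = "mif_variable_parameter")
}

#' Confidence value
#' @param unit [mif_cv()] describing the confidence scheme.
#' @param value Text value.
#' @return An object of class `mif_confidence`.
#' @export
mif_confidence <- function(unit, value) {
  if (!inherits(unit, "mif_cv")) mif_abort("`unit` must be a <mif_cv>")
  chk_string(value, "value")
  structure(list(unit = unit, value = value), class = "mif_confidence")
}

#' Experiment description
#'
#' @param id Entry-unique integer id.
#' @param bibref Required [mif_bibref()].
#' @param interaction_detection_method Required [mif_cv()].
#' @param names Optional [mif_names()].
#' @param host_organisms List of [mif_organism()].
#' @param participant_identification_method,feature_detection_method
#'   Optional [mif_cv()] terms.
#' @param variable_parameters List of [mif_variable_parameter()] —
#'   the level 3.0 description of dynamic experimental conditions.
#' @param confidences,attributes Lists of [mif_confidence()] /
#'   [mif_attribute()].
#' @param xref Optional [mif_xref()].
#' @return An object of class `mif_experiment`.
#' @export
mif_experiment <- function(id, bibref, interaction_detection_method,
                           names = NULL, host_organisms = list(),
                           participant_identification_method = NULL,
                           feature_detection_method = NULL,
                           variable_parameters = list(),
                           confidences = list(), attributes = list(),
                           xref = NULL) {
  id <- chk_id(id, "id")
  if (!inherits(bibref, "mif_bibref")) mif_abort("`bibref` is required")
  if (!inherits(interaction_detection_method, "mif_cv")) {
    mif_abort("`interaction_detection_method` is required")
  }
  structure(list(
    id = id, names = names, bibref = bibref, xref = xref,
    host_organisms = chk_list_of(host_organisms, "mif_organism",
                                 "host_organisms"),
    interaction_detection_method = interaction_detection_method,
    participant_identification_method = participant_identification_method,
    feature_detection_method = feature_detection_method,
    variable_parameters = chk_list_of(variable_parameters,
                                      "mif_variable_parameter",
                                      "variable_parameters"),
    confidences = chk_list_of(confidences, "mif_confidence", "confidences"),
    attributes = chk_list_of(attributes, "mif_attribute", "attributes")
  ), class = "mif_experiment")
}

#' Interactor (molecule)
#'
#' @param id Entry-unique integer id.
#' @param interactor_type Required [mif_cv()] (protein, dna, molecule
#'   set, complex, ...).
#' @param names,xref,organism,sequence,attributes Optional components.
#' @return An object of class `mif_interactor`.
#' @export
mif_interactor <- function(id, interactor_type, names = NULL, xref = NULL,
                           organism = NULL, sequence = NULL,
                           attributes = list()) {
  id <- chk_id(id, "id")
  if (!inherits(interactor_type, "mif_cv")) {
    mif_abort("`interactor_type` is required")
  }
  chk_string(sequence, "sequence", allow_null = TRUE)
  structure(list(id = id, names = names, xref = xref,
                 interactor_type = interactor_type, organism = organism,
                 sequence = sequence,
                 attributes = chk_list_of(attributes, "mif_attribute",
                                          "attributes")),
            class = "mif_interactor")
}

# ---- positions --------------------------------------------------------------

#' Feature-range positions
#'
#' Coordinates are 1-based inclusive on the interactor sequence.  Negative
#' values are relative upstream coordinates (promoter regions); 0 is
#' accepted by the model but flagged by the validator, since biological
#' coordinate conventions skip it.  Signed values are a level 3.0 feature —
#' level 2.5 positions are unsigned.
#'
#' @param value Signed integer coordinate.
#' @return An object of class `mif_position`.
#' @export
mif_pos_exact <- function(value) {
  value <- chk_id(value, "value")
  structure(list(kind = "exact", value = value), class = "mif_position")
}

#' @rdname mif_pos_exact
#' @param start,end Signed integer bounds of a fuzzy interval, start <= end.
#' @export
mif_pos_interval <- function(start, end) {
  start <- chk_id(start, "start")
  end <- chk_id(end, "end")
  if (start > end) mif_abort("interval start must be <= end")
  structure(list(kind = "interval", start = start, end = end),
            class = "mif_position")
}

#' @rdname mif_pos_exact
#' @export
mif_pos_unstated <- function() {
  structure(list(kind = "unstated"), class = "mif_position")
}

#' Resulting sequence of a mutation feature
#'
#' Captures the actual sequence change of a mutation: either both the
#' original and the new sequence, or a cross-reference (e.g. to a SNP
#' record) standing in for them — the sequences are not required if an
#' xref is provided.
#'
#' @param original,new Optional sequence strings (IUPAC letters).
#' @param xref Optional [mif_xref()].
#' @return An object of class `mif_resulting_sequence`.
#' @export
mif_resulting_sequence <- function(original = NULL, new = NULL, xref = NULL) {
  chk_string(original, "original", allow_null = TRUE)
  chk_string(new, "new", allow_null = TRUE)
  has_seqs <- !is.null(original) && !is.null(new)
  if (!has_seqs && is.null(xref)) {
    mif_abort(paste0("a resulting sequence needs either both original and ",
                     "new sequences or an xref"))
  }
  if (!is.null(xref) && !inherits(xref, "mif_xref")) {
    mif_abort("`xref` must be a <mif_xref>")
  }
  structure(list(original = original, new = new, xref = xref),
            class = "mif_resulting_sequence")
}

#' Feature range
#'
#' @param begin_status,end_status [mif_cv()] range-status terms
#'   (certain, undetermined, ...).
#' @param begin,end [mif_pos_exact()] / [mif_pos_interval()] /
#'   [mif_pos_unstated()] positions.
#' @param is_link Whether the range links two positions (default FALSE).
#' @param resulting_sequence Optional [mif_resulting_sequence()].
#' @return An object of class `mif_feature_range`.
#' @export
mif_feature_range <- function(begin_status, begin, end_status, end,
                              is_link = FALSE, resulting_sequence = NULL) {
  for (st in list(begin_status, end_status)) {
    if (!inherits(st, "mif_cv")) mif_abort("range statuses must be <mif_cv>")
  }
  for (p in list(begin, end)) {
    if (!inherits(p, "mif_position")) mif_abort("positions must be <mif_position>")
  }
  chk_flag(is_link, "is_link")
  if (!is.null(resulting_sequence) &&
      !inherits(resulting_sequence, "mif_resulting_sequence")) {
    mif_abort("`resulting_sequence` must be a <mif_resulting_sequence>")
  }
  structure(list(begin_status = begin_status, begin = begin,
                 end_status = end_status, end = end, is_link = is_link,
                 resulting_sequence = resulting_sequence),
            class = "mif_feature_range")
}

#' Sequence feature on a participant
#'
#' Level 3.0 extends features with a repeatable detection method (a PTM
#' seen both by a specific antibody and by mass spectrometry), an optional
#' feature role (prerequisite-PTM, observed-PTM, ...; must carry an MI
#' accession) and feature-level kinetic parameters tied to a mutation.
#'
#' @param id Entry-unique integer id.
#' @param ranges Non-empty list of [mif_feature_range()] objects.
#' @param feature_type,feature_role Optional [mif_cv()] terms.
#' @param detection_methods List of [mif_cv()] terms (repeatable,
#'   document order preserved).
#' @param parameters List of [mif_parameter()] objects.
#' @param names,xref,attributes Optional components.
#' @return An object of class `mif_feature`.
#' @export
mif_feature <- function(id, ranges, feature_type = NULL, feature_role = NULL,
                        detection_methods = list(), parameters = list(),
                        names = NULL, xref = NULL, attributes = list()) {
  id <- chk_id(id, "id")
  ranges <- chk_list_of(ranges, "mif_feature_range", "ranges")
  if (length(ranges) == 0L) mif_abort("a feature needs at least one range")
  if (!is.null(feature_role) && !inherits(feature_role, "mif_cv")) {
    mif_abort("`feature_role` must be a <mif_cv>")
  }
  structure(list(id = id, names = names, xref = xref,
                 feature_type = feature_type, feature_role = feature_role,
                 detection_methods = chk_list_of(detection_methods, "mif_cv",
                                                 "detection_methods"),
                 ranges = ranges,
                 parameters = chk_list_of(parameters, "mif_parameter",
                                          "parameters"),
                 attributes = chk_list_of(attributes, "mif_attribute",
                                          "attributes")),
            class = "mif_feature")
}

# ---- stoichiometry ----------------------------------------------------------

#' Participant stoichiometry
#'
#' Level 3.0 stoichiometry is either a mean decimal value or a decimal
#' range; values must be >= 0.  The lexical form is kept so decimals
#' round-trip unchanged.
#'
#' @param value Mean stoichiometry, decimal >= 0.
#' @param lexical Optional exact string form.
#' @return An object of class `mif_stoichiometry`.
#' @export
mif_stoich_mean <- function(value, lexical = NULL) {
  value <- chk_num(value, "value")
  if (value < 0) mif_abort("stoichiometry values must be >= 0")
  chk_string(lexical, "lexical", allow_null = TRUE)
  structure(list(kind = "mean", value = value, value_lexical = lexical),
            class = "mif_stoichiometry")
}

#' @rdname mif_stoich_mean
#' @param min_value,max_value Decimal bounds, `0 <= min_value <= max_value`.
#' @param min_lexical,max_lexical Optional exact string forms.
#' @export
mif_stoich_range <- function(min_value, max_value,
                             min_lexical = NULL, max_lexical = NULL) {
  min_value <- chk_num(min_value, "min_value")
  max_value <- chk_num(max_value, "max_value")
  if (min_value < 0 || max_value < 0) {
    mif_abort("stoichiometry values must be >= 0")
  }
  if (min_value > max_value) {
    mif_abort("stoichiometry range min must be <= max")
  }
  structure(list(kind = "range", min_value = min_value,
                 max_value = max_value, min_lexical = min_lexical,
                 max_lexical = max_lexical),
            class = "mif_stoichiometry")
}

#' @rdname mif_stoich_mean
#' @export
mif_stoich_unstated <- function() {
  structure(list(kind = "unstated"), class = "mif_stoichiometry")
}

# ---- candidate sets ---------------------------------------------------------

#' Interactor candidate within a molecule set
#'
#' @param id Entry-unique integer id.
#' @param interactor_ref Id of the interactor this candidate resolves to.
#' @param features Optional list of [mif_feature()] binding features
#'   specific to this candidate.
#' @return An object of class `mif_candidate`.
#' @export
mif_candidate <- function(id, interactor_ref, features = list()) {
  structure(list(id = chk_id(id, "id"),
                 interactor_ref = chk_id(interactor_ref, "interactor_ref"),
                 features = chk_list_of(features, "mif_feature", "features")),
            class = "mif_candidate")
}

#' Molecule set (interactor candidate list)
#'
#' A participant that is one of several indistinguishable molecules —
#' e.g. human calmodulin, an identical protein produced by the CALM1,
#' CALM2 and CALM3 genes.
#'
#' @param set_type [mif_cv()] molecule-set type term.
#' @param candidates Non-empty list of [mif_candidate()] objects.
#' @return An object of class `mif_candidate_set`.
#' @export
mif_candidate_set <- function(set_type, candidates) {
  if (!inherits(set_type, "mif_cv")) mif_abort("`set_type` must be a <mif_cv>")
  candidates <- chk_list_of(candidates, "mif_candidate", "candidates")
  if (length(candidates) == 0L) {
    mif_abort("a candidate set needs at least one candidate")
  }
  structure(list(set_type = set_type, candidates = candidates),
            class = "mif_candidate_set")
}

# ---- participants -----------------------------------------------------------

#' Participant entity
#'
#' Exactly one of the four branches: a reference to an interactor, a
#' reference to another interaction (sub-complex), or a molecule set.
#' Inline interactors read from extended-form documents are hoisted to the
#' entry interactor list, so the in-memory entity is always a reference or
#' a candidate set.
#'
#' @param interactor_ref,interaction_ref Integer ids (one of).
#' @param candidate_set A [mif_candidate_set()] (one of).
#' @return An object of class `mif_entity`.
#' @export
mif_entity <- function(interactor_ref = NULL, interaction_ref = NULL,
                       candidate_set = NULL) {
  n_set <- sum(!is.null(interactor_ref), !is.null(interaction_ref),
               !is.null(candidate_set))
  if (n_set != 1L) {
    mif_abort("exactly one entity branch must be set")
  }
  if (!is.null(candidate_set)) {
    if (!inherits(candidate_set, "mif_candidate_set")) {
      mif_abort("`candidate_set` must be a <mif_candidate_set>")
    }
    return(structure(list(kind = "candidate_set", set = candidate_set),
                     class = "mif_entity"))
  }
  if (!is.null(interactor_ref)) {
    return(structure(list(kind = "interactor_ref",
                          ref = chk_id(interactor_ref, "interactor_ref")),
                     class = "mif_entity"))
  }
  structure(list(kind = "interaction_ref",
                 ref = chk_id(interaction_ref, "interaction_ref")),
            class = "mif_entity")
}

#' Interaction participant
#'
#' @param id Entry-unique integer id.
#' @param entity A [mif_entity()].
#' @param biological_role Optional [mif_cv()].
#' @param experimental_roles,identification_methods,experimental_preparations
#'   Lists of [mif_cv()] terms.
#' @param features List of [mif_feature()] objects.
#' @param host_organisms,confidences,parameters,attributes Optional lists.
#' @param stoichiometry A [mif_stoich_mean()], [mif_stoich_range()] or
#'   [mif_stoich_unstated()] (default unstated).
#' @param names,xref Optional components.
#' @return An object of class `mif_participant`.
#' @export
mif_participant <- function(id, entity, biological_role = NULL,
                            experimental_roles = list(),
                            identification_methods = list(),
                            experimental_preparations = list(),
                            features = list(), host_organisms = list(),
                            confidences = list(), parameters = list(),
                            stoichiometry = mif_stoich_unstated(),
                            names = NULL, xref = NULL, attributes = list()) {
  id <- chk_id(id, "id")
  if (!inherits(entity, "mif_entity")) mif_abort("`entity` must be a <mif_entity>")
  if (!is.null(biological_role) && !inherits(biological_role, "mif_cv")) {
    mif_abort("`biological_role` must be a <mif_cv>")
  }
  if (!inherits(stoichiometry, "mif_stoichiometry")) {
    mif_abort("`stoichiometry` must be a <mif_stoichiometry>")
  }
  structure(list(
    id = id, names = names, xref = xref, entity = entity,
    biological_role = biological_role,
    experimental_roles = chk_list_of(experimental_roles, "mif_cv",
                                     "experimental_roles"),
    identification_methods = chk_list_of(identification_methods, "mif_cv",
                                         "identification_methods"),
    experimental_preparations = chk_list_of(experimental_preparations,
                                            "mif_cv",
                                            "experimental_preparations"),
    features = chk_list_of(features, "mif_feature", "features"),
    host_organisms = chk_list_of(host_organisms, "mif_organism",
                                 "host_organisms"),
    confidences = chk_list_of(confidences, "mif_confidence", "confidences"),
    parameters = chk_list_of(parameters, "mif_parameter", "parameters"),
    stoichiometry = stoichiometry,
    attributes = chk_list_of(attributes, "mif_attribute", "attributes")
  ), class = "mif_participant")
}

# ---- interactions -----------------------------------------------------------

#' Evidence (experimental) interaction
#'
#' @param id Entry-unique integer id.
#' @param experiment_refs Integer vector of experiment ids (>= 1 for a
#'   validator-clean document).
#' @param participants List of [mif_participant()] objects.
#' @param interaction_types List of [mif_cv()] terms.
#' @param negative,intra_molecular Booleans, default FALSE.
#' @param inferred_interactions List of inferred-interaction groups; each
#'   group is a list of items `list(kind = "participant"|"feature", ref = id)`.
#' @param condition_sets List of integer vectors of variable-value ids:
#'   each vector is one combination of experimental conditions under which
#'   the interaction was observed; an empty list means unconditioned.
#' @param confidences,parameters,attributes Optional lists.  Wild-type
#'   kinetic parameters stay at the interaction level; mutation-linked ones
#'   belong on the feature.
#' @param names,xref Optional components.
#' @return An object of class `mif_interaction`.
#' @export
mif_interaction <- function(id, experiment_refs, participants,
                            interaction_types = list(), negative = FALSE,
                            intra_molecular = FALSE,
                            inferred_interactions = list(),
                            condition_sets = list(), confidences = list(),
                            parameters = list(), attributes = list(),
                            names = NULL, xref = NULL) {
  id <- chk_id(id, "id")
  experiment_refs <- vapply(as.list(experiment_refs), chk_id,
                            integer(1), what = "experiment_refs")
  chk_flag(negative, "negative")
  chk_flag(intra_molecular, "intra_molecular")
  condition_sets <- lapply(condition_sets, function(s) {
    vapply(as.list(s), chk_id, integer(1), what = "condition_sets")
  })
  structure(list(
    id = id, names = names, xref = xref,
    experiment_refs = experiment_refs,
    participants = chk_list_of(participants, "mif_participant",
                               "participants"),
    inferred_interactions = inferred_interactions,
    interaction_types = chk_list_of(interaction_types, "mif_cv",
                                    "interaction_types"),
    negative = negative, intra_molecular = intra_molecular,
    confidences = chk_list_of(confidences, "mif_confidence", "confidences"),
    parameters = chk_list_of(parameters, "mif_parameter", "parameters"),
    condition_sets = condition_sets,
    attributes = chk_list_of(attributes, "mif_attribute", "attributes")
  ), class = "mif_interaction")
}

#' Cooperative effect (allostery / pre-assembly)
#'
#' Describes how the owning abstract interaction influences other
#' interactions: allostery acts through a distal site of the same molecule,
#' pre-assembly through generation or abrogation of a binding site.
#'
#' @param affected_refs Non-empty integer vector of ids of the affected
#'   interactions (must resolve within the same entry).
#' @param outcome [mif_cv()] outcome term (positive / negative effect).
#' @param response Optional [mif_cv()].
#' @param evidence List of `list(bibref = <mif_bibref>, methods =
#'   list(<mif_cv>))` records: the publications and methods the effect was
#'   inferred from.
#' @param allosteric_molecule_ref Participant id of the allosteric molecule
#'   (allostery only).
#' @param effector For allostery: `list(kind = "molecule", ref =
#'   participant id)` or `list(kind = "feature_modification", ref = feature
#'   id)`.
#' @param allostery_type,allosteric_mechanism Optional [mif_cv()] terms.
#' @return An object of class `mif_cooperative_effect`.
#' @export
mif_allostery <- function(affected_refs, outcome,
                          allosteric_molecule_ref, effector,
                          response = NULL, evidence = list(),
                          allostery_type = NULL,
                          allosteric_mechanism = NULL) {
  eff <- new_coop_effect("allostery", affected_refs, outcome, response,
                         evidence)
  eff$allosteric_molecule_ref <- chk_id(allosteric_molecule_ref,
                                        "allosteric_molecule_ref")
  if (!is.list(effector) || is.null(effector$kind) ||
      !effector$kind %in% c("molecule", "feature_modification")) {
    mif_abort("`effector` must be list(kind = 'molecule'|'feature_modification', ref =)")
  }
  eff$effector <- list(kind = effector$kind,
                       ref = chk_id(effector$ref, "effector$ref"))
  eff$allostery_type <- allostery_type
  eff$allosteric_mechanism <- allosteric_mechanism
  eff
}

#' @rdname mif_allostery
#' @export
mif_preassembly <- function(affected_refs, outcome, response = NULL,
                            evidence = list()) {
  new_coop_effect("preassembly", affected_refs, outcome, response, evidence)
}

new_coop_effect <- function(kind, affected_refs, outcome, response,
                            evidence) {
  affected_refs <- vapply(as.list(affected_refs), chk_id, integer(1),
                          what = "affected_refs")
  if (length(affected_refs) == 0L) {
    mif_abort("a cooperative effect needs at least one affected interaction")
  }
  if (!inherits(outcome, "mif_cv")) mif_abort("`outcome` must be a <mif_cv>")
  if (!is.null(response) && !inherits(response, "mif_cv")) {
    mif_abort("`response` must be a <mif_cv>")
  }
  for (ev in evidence) {
    if (!is.list(ev) || !inherits(ev$bibref, "mif_bibref")) {
      mif_abort("each evidence record needs a bibref")
    }
  }
  structure(list(kind = kind, evidence = evidence,
                 affected_refs = affected_refs, outcome = outcome,
                 response = response),
            class = "mif_cooperative_effect")
}

#' Abstract (modelled) interaction
#'
#' An evidence-free interaction assembled from multiple experiments or
#' publications — a curated reference complex, or the owner of cooperative
#' effects.  It carries no experiment references; participants may
#' reference sub-complexes through interaction refs, supporting the
#' hierarchical build-up of complexes.
#'
#' @param id Entry-unique integer id.
#' @param participants List of [mif_participant()] objects.
#' @param interactor_type Optional [mif_cv()] (e.g. protein complex).
#' @param interaction_type Optional [mif_cv()].
#' @param organism Optional [mif_organism()].
#' @param binding_features List of integer vectors of feature ids that
#'   together form one binding region.
#' @param cooperative_effects List of [mif_allostery()] /
#'   [mif_preassembly()] objects.
#' @param evidence_type Optional [mif_cv()].
#' @param names,xref,attributes Optional components.
#' @return An object of class `mif_abstract_interaction`.
#' @export
mif_abstract_interaction <- function(id, participants = list(),
                                     interactor_type = NULL,
                                     interaction_type = NULL,
                                     organism = NULL,
                                     binding_features = list(),
                                     cooperative_effects = list(),
                                     evidence_type = NULL, names = NULL,
                                     xref = NULL, attributes = list()) {
  id <- chk_id(id, "id")
  binding_features <- lapply(binding_features, function(s) {
    vapply(as.list(s), chk_id, integer(1), what = "binding_features")
  })
  structure(list(
    id = id, names = names, xref = xref,
    interactor_type = interactor_type, interaction_type = interaction_type,
    organism = organism,
    participants = chk_list_of(participants, "mif_participant",
                               "participants"),
    binding_features = binding_features,
    cooperative_effects = chk_list_of(cooperative_effects,
                                      "mif_cooperative_effect",
                                      "cooperative_effects"),
    evidence_type = evidence_type,
    experiment_refs = integer(0),  # always empty for a valid document
    attributes = chk_list_of(attributes, "mif_attribute", "attributes")
  ), class = "mif_abstract_interaction")
}

# ---- entry / document -------------------------------------------------------

#' Data source of an entry
#' @param names Optional [mif_names()].
#' @param xref,bibref,attributes,release_date Optional components.
#' @return An object of class `mif_source`.
#' @export
mif_source <- function(names = NULL, xref = NULL, bibref = NULL,
                       attributes = list(), release_date = NULL) {
  chk_string(release_date, "release_date", allow_null = TRUE)
  structure(list(names = names, xref = xref, bibref = bibref,
                 attributes = chk_list_of(attributes, "mif_attribute",
                                          "attributes"),
                 release_date = release_date),
            class = "mif_source")
}

#' Availability statement
#' @param id Entry-unique integer id.
#' @param value Text of the availability statement.
#' @return An object of class `mif_availability`.
#' @export
mif_availability <- function(id, value) {
  structure(list(id = chk_id(id, "id"), value = chk_string(value, "value")),
            class = "mif_availability")
}

#' Entry: one self-contained block of interaction data
#'
#' All ids within an entry share one integer namespace (experiments,
#' interactors, interactions, participants, features, candidates, variable
#' values, availabilities) and every reference must resolve inside the
#' entry.
#'
#' @param experiments List of [mif_experiment()] objects.
#' @param interactors List of [mif_interactor()] objects.
#' @param interactions Ordered list of [mif_interaction()] and
#'   [mif_abstract_interaction()] objects.
#' @param source Optional [mif_source()].
#' @param availabilities List of [mif_availability()] objects.
#' @param attributes List of [mif_attribute()] objects.
#' @return An object of class `mif_entry`.
#' @export
mif_entry <- function(experiments = list(), interactors = list(),
                      interactions = list(), source = NULL,
                      availabilities = list(), attributes = list()) {
  for (i in interactions) {
    if (!inherits(i, "mif_interaction") &&
        !inherits(i, "mif_abstract_interaction")) {
      mif_abort("interactions must be <mif_interaction> or <mif_abstract_interaction>")
    }
  }
  structure(list(
    source = source,
    availabilities = chk_list_of(availabilities, "mif_availability",
                                 "availabilities"),
    experiments = chk_list_of(experiments, "mif_experiment", "experiments"),
    interactors = chk_list_of(interactors, "mif_interactor", "interactors"),
    interactions = unname(as.list(interactions)),
    attributes = chk_list_of(attributes, "mif_attribute", "attributes")
  ), class = "mif_entry")
}

#' PSI-MI document (entry set)
#'
#' @param entries Non-empty list of [mif_entry()] objects.
#' @param level Format level, `"3.0"` (default) or `"2.5"`.
#' @return An object of class `mif_document`.
#' @export
#' @examples
#' doc <- mif_document(mif_entry())
#' doc$level
mif_document <- function(entries, level = "3.0") {
  if (inherits(entries, "mif_entry")) entries <- list(entries)
  entries <- chk_list_of(entries, "mif_entry", "entries")
  if (length(entries) == 0L) mif_abort("a document needs at least one entry")
  if (!level %in% c("2.5", "3.0")) {
    mif_abort("`level` must be \"2.5\" or \"3.0\"")
  }
  structure(list(entries = entries, level = level), class = "mif_document")
}

#' @export
print.mif_document <- function(x, ...) {
  cat(sprintf("<PSI-MI %s document: %d entr%s>\n", x$level,
              length(x$entries), if (length(x$entries) == 1) "y" else "ies"))
  for (i in seq_along(x$entries)) {
    e <- x$entries[[i]]
    n_ev <- sum(vapply(e$interactions, inherits, logical(1),
                       "mif_interaction"))
    n_ab <- length(e$interactions) - n_ev
    cat(sprintf(
      "  entry %d: %d experiment(s), %d interactor(s), %d evidence + %d abstract interaction(s)\n",
      i, length(e$experiments), length(e$interactors), n_ev, n_ab))
  }
  invisible(x)
}
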