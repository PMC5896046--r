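# Deterministic fixture documents: one golden document per supported use
# case (a..k) and a seeded random generator for property tests.  Every
# fixture is validator-clean at 3.0 and carries an expected-loss manifest
# (category -> count) describing what a 2.5 downgrade must report.

FIXTURE_CASES <- letters[1:11]

WORDS <- c("alder", "birch", "cedar", "dunlin", "elm", "fir", "gorse",
           "hazel", "iris", "juniper", "kestrel", "larch", "maple",
           "nettle", "osier", "pine", "quince", "rowan", "sorrel",
           "teasel", "ulex", "vetch", "willow", "yarrow")

cv_protein <- function() mif_cv("protein", mi_accession = "MI:0326")
cv_dna <- function() mif_cv("dna", "deoxyribonucleic acid", "MI:0319")
cv_complex <- function() mif_cv("complex", mi_accession = "MI:0314")
cv_bait <- function() mif_cv("bait", mi_accession = "MI:0496")
cv_prey <- function() mif_cv("prey", mi_accession = "MI:0498")
cv_certain <- function() mif_cv("certain", mi_accession = "MI:0335")
cv_assoc <- function() mif_cv("physical association", mi_accession = "MI:0915")
cv_two_hybrid <- function() mif_cv("two hybrid", mi_accession = "MI:0018")
cv_coip <- function() mif_cv("coimmunoprecipitation", mi_accession = "MI:0019")

bib_pubmed <- function(pmid) {
  mif_bibref(xref = mif_xref(mif_dbref("pubmed", pmid)))
}

human <- function() mif_organism(9606, names = mif_names("human"))

new_id_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function() {
    env$n <- env$n + 1L
    env$n
  }
}

simple_feature <- function(id, type = mif_cv("binding site",
                                             mi_accession = "MI:0117"),
                           from = 10L, to = 25L, ...) {
  mif_feature(
    id = id, feature_type = type,
    ranges = list(mif_feature_range(cv_certain(), mif_pos_exact(from),
                                    cv_certain(), mif_pos_exact(to))),
    ...
  )
}

# assemble the common one-experiment, binary-interaction scaffold that the
# simple use cases decorate
uc_scaffold <- function(nid, detection = cv_two_hybrid(),
                        pmid = "7000001", bibref = NULL,
                        variable_parameters = list()) {
  ex <- mif_experiment(
    id = nid(), bibref = bibref %||% bib_pubmed(pmid),
    interaction_detection_method = detection,
    host_organisms = list(human()),
    variable_parameters = variable_parameters
  )
  i1 <- mif_interactor(nid(), cv_protein(), names = mif_names("alder_p"),
                       xref = mif_xref(mif_dbref("uniprotkb", "X00001")),
                       organism = human())
  i2 <- mif_interactor(nid(), cv_protein(), names = mif_names("birch_p"),
                       xref = mif_xref(mif_dbref("uniprotkb", "X00002")),
                       organism = human())
  list(experiment = ex, interactors = list(i1, i2))
}

binary_interaction <- function(nid, sc, p1_args = list(), p2_args = list(),
                               ...) {
  p1 <- do.call(mif_participant, c(list(
    id = nid(), entity = mif_entity(interactor_ref = sc$interactors[[1L]]$id),
    experimental_roles = list(cv_bait())), p1_args))
  p2 <- do.call(mif_participant, c(list(
    id = nid(), entity = mif_entity(interactor_ref = sc$interactors[[2L]]$id),
    experimental_roles = list(cv_prey())), p2_args))
  mif_interaction(id = nid(), experiment_refs = sc$experiment$id,
                  participants = list(p1, p2),
                  interaction_types = list(cv_assoc()), ...)
}

manifest <- function(...) {
  v <- c(...)
  stopifnot(all(names(v) %in% LOSS_CATEGORIES))
  v
}

finish_case <- function(doc, loss) {
  attr(doc, "loss_manifest") <- loss
  doc
}

uc_a_negative_range <- function() {
  nid <- new_id_pool()
  ex <- mif_experiment(nid(), bib_pubmed("7000011"),
                       mif_cv("affinity chromatography technology",
                              mi_accession = "MI:0004"),
                       host_organisms = list(human()))
  gene <- mif_interactor(nid(), cv_dna(),
                         names = mif_names("cedar_promoter",
                                           "cedar gene upstream region"),
                         organism = human())
  tf <- mif_interactor(nid(), cv_protein(), names = mif_names("dunlin_tf"),
                       organism = human())
  promoter_feature <- mif_feature(
    id = nid(), names = mif_names("promoter region"),
    feature_type = mif_cv("binding site", mi_accession = "MI:0117"),
    ranges = list(mif_feature_range(cv_certain(), mif_pos_exact(-2000L),
                                    cv_certain(), mif_pos_exact(-1L)))
  )
  ia <- mif_interaction(
    id = nid(), experiment_refs = ex$id,
    participants = list(
      mif_participant(nid(), mif_entity(interactor_ref = gene$id),
                      features = list(promoter_feature)),
      mif_participant(nid(), mif_entity(interactor_ref = tf$id),
                      experimental_roles = list(cv_bait()))
    ),
    interaction_types = list(cv_assoc())
  )
  doc <- mif_document(mif_entry(experiments = list(ex),
                                interactors = list(gene, tf),
                                interactions = list(ia)))
  finish_case(doc, manifest(NEGATIVE_POSITION = 1L))
}

uc_b_resulting_sequence <- function() {
  nid <- new_id_pool()
  sc <- uc_scaffold(nid, pmid = "7000012")
  mut <- mif_feature(
    id = nid(), names = mif_names("K128R mutation"),
    feature_type = mif_cv("mutation", mi_accession = "MI:0118"),
    ranges = list(mif_feature_range(
      cv_certain(), mif_pos_exact(128L), cv_certain(), mif_pos_exact(128L),
      resulting_sequence = mif_resulting_sequence(
        original = "K", new = "R",
        xref = mif_xref(mif_dbref("ensembl", "rs7000012")))))
  )
  ia <- binary_interaction(nid, sc, p2_args = list(features = list(mut)))
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(RESULTING_SEQUENCE = 1L))
}

uc_c_multi_detection <- function() {
  nid <- new_id_pool()
  sc <- uc_scaffold(nid, detection = cv_coip(), pmid = "7000013")
  ptm <- mif_feature(
    id = nid(), names = mif_names("phosphotyrosine site"),
    feature_type = mif_cv("observed-ptm", mi_accession = "MI:0925"),
    detection_methods = list(
      mif_cv("identification by antibody", mi_accession = "MI:0421"),
      mif_cv("detection by mass spectrometry", mi_accession = "MI:0943")),
    ranges = list(mif_feature_range(cv_certain(), mif_pos_exact(77L),
                                    cv_certain(), mif_pos_exact(77L)))
  )
  ia <- binary_interaction(nid, sc, p1_args = list(features = list(ptm)))
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(EXTRA_DETECTION_METHODS = 1L))
}

uc_d_feature_role <- function() {
  nid <- new_id_pool()
  sc <- uc_scaffold(nid, detection = cv_coip(), pmid = "7000014")
  ptm <- mif_feature(
    id = nid(), names = mif_names("required phosphosite"),
    feature_type = mif_cv("observed-ptm", mi_accession = "MI:0925"),
    feature_role = mif_cv("prerequisite-ptm", mi_accession = "MI:0638"),
    ranges = list(mif_feature_range(cv_certain(), mif_pos_exact(42L),
                                    cv_certain(), mif_pos_exact(42L)))
  )
  ia <- binary_interaction(nid, sc, p1_args = list(features = list(ptm)))
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(FEATURE_ROLE = 1L))
}

uc_e_feature_parameters <- function() {
  nid <- new_id_pool()
  sc <- uc_scaffold(nid, pmid = "7000015")
  mut <- mif_feature(
    id = nid(), names = mif_names("affinity-reducing mutation"),
    feature_type = mif_cv("mutation", mi_accession = "MI:0118"),
    ranges = list(mif_feature_range(cv_certain(), mif_pos_exact(55L),
                                    cv_certain(), mif_pos_exact(55L))),
    parameters = list(mif_parameter("kd", factor = 3.1, exponent = -6L,
                                    unit = "molar",
                                    experiment_ref = sc$experiment$id,
                                    factor_lexical = "3.1"))
  )
  # wild-type affinity stays at the interaction level
  ia <- binary_interaction(
    nid, sc, p2_args = list(features = list(mut)),
    parameters = list(mif_parameter("kd", factor = 2.4, exponent = -9L,
                                    unit = "molar",
                                    experiment_ref = sc$experiment$id,
                                    factor_lexical = "2.4")))
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(FEATURE_PARAMETERS = 1L))
}

uc_f_variable_parameters <- function() {
  nid <- new_id_pool()
  vv_ids <- integer(0)
  ex <- mif_experiment(
    id = nid(), bibref = bib_pubmed("7000016"),
    interaction_detection_method = cv_coip(),
    host_organisms = list(human()),
    variable_parameters = list(mif_variable_parameter(
      description = "hours post-Sendai viral infection",
      unit = mif_cv("hour"),
      values = {
        vals <- lapply(seq_len(4L), function(k) {
          id <- nid()
          vv_ids <<- c(vv_ids, id)
          mif_variable_value(id, value = as.character((k - 1L) * 4L),
                             order = k)
        })
        vals
      }))
  )
  stat6 <- mif_interactor(nid(), cv_protein(), names = mif_names("stat6"),
                          organism = human())
  partners <- lapply(c("elm_p", "fir_p", "gorse_p"), function(nm) {
    mif_interactor(nid(), cv_protein(), names = mif_names(nm),
                   organism = human())
  })
  interactions <- lapply(seq_len(3L), function(k) {
    mif_interaction(
      id = nid(), experiment_refs = ex$id,
      participants = list(
        mif_participant(nid(), mif_entity(interactor_ref = stat6$id),
                        experimental_roles = list(cv_bait())),
        mif_participant(nid(),
                        mif_entity(interactor_ref = partners[[k]]$id),
                        experimental_roles = list(cv_prey()))),
      interaction_types = list(cv_assoc()),
      condition_sets = list(vv_ids[k + 1L])  # each seen at a distinct time
    )
  })
  doc <- mif_document(mif_entry(experiments = list(ex),
                                interactors = c(list(stat6), partners),
                                interactions = interactions))
  finish_case(doc, manifest(VARIABLE_PARAMETERS = 4L))
}

uc_g_abstract_complex <- function() {
  nid <- new_id_pool()
  subunits <- lapply(c("hazel_a", "hazel_b", "hazel_c"), function(nm) {
    mif_interactor(nid(), cv_protein(), names = mif_names(nm),
                   organism = human())
  })
  participants <- lapply(subunits, function(su) {
    mif_participant(nid(), mif_entity(interactor_ref = su$id),
                    biological_role = mif_cv("unspecified role",
                                             mi_accession = "MI:0499"))
  })
  complex <- mif_abstract_interaction(
    id = nid(), names = mif_names("hazel core complex"),
    xref = mif_xref(mif_dbref("complex portal", "CPX-70001")),
    interactor_type = cv_complex(),
    interaction_type = cv_assoc(),
    organism = human(),
    participants = participants,
    evidence_type = mif_cv("inferred from experimental data")
  )
  doc <- mif_document(mif_entry(interactors = subunits,
                                interactions = list(complex)))
  finish_case(doc, manifest(ABSTRACT_INTERACTION = 1L))
}

uc_h_cooperative_allostery <- function() {
  nid <- new_id_pool()
  ex <- mif_experiment(nid(), bib_pubmed("7000018"), cv_two_hybrid(),
                       host_organisms = list(human()))
  enzyme <- mif_interactor(nid(), cv_protein(), names = mif_names("iris_e"),
                           organism = human())
  modulator <- mif_interactor(nid(), cv_protein(),
                              names = mif_names("juniper_m"),
                              organism = human())
  substrate <- mif_interactor(nid(), cv_protein(),
                              names = mif_names("kestrel_s"),
                              organism = human())
  affected <- mif_interaction(
    id = nid(), experiment_refs = ex$id,
    participants = list(
      mif_participant(nid(), mif_entity(interactor_ref = enzyme$id),
                      experimental_roles = list(cv_bait())),
      mif_participant(nid(), mif_entity(interactor_ref = substrate$id),
                      experimental_roles = list(cv_prey()))),
    interaction_types = list(cv_assoc())
  )
  p_enzyme <- mif_participant(nid(), mif_entity(interactor_ref = enzyme$id))
  p_mod <- mif_participant(nid(), mif_entity(interactor_ref = modulator$id))
  allo <- mif_allostery(
    affected_refs = affected$id,
    outcome = mif_cv("positive cooperative effect"),
    response = mif_cv("altered physicochemical compatibility"),
    allosteric_molecule_ref = p_enzyme$id,
    effector = list(kind = "molecule", ref = p_mod$id),
    evidence = list(list(
      bibref = bib_pubmed("7000019"),
      methods = list(mif_cv("inferred by author", mi_accession = "MI:0363"))))
  )
  abstract <- mif_abstract_interaction(
    id = nid(), names = mif_names("iris-juniper allosteric module"),
    interactor_type = cv_complex(),
    participants = list(p_enzyme, p_mod),
    cooperative_effects = list(allo)
  )
  doc <- mif_document(mif_entry(experiments = list(ex),
                                interactors = list(enzyme, modulator,
                                                   substrate),
                                interactions = list(affected, abstract)))
  finish_case(doc, manifest(ABSTRACT_INTERACTION = 1L,
                            COOPERATIVE_EFFECT = 1L))
}

uc_i_molecule_set <- function() {
  nid <- new_id_pool()
  ex <- mif_experiment(nid(), bib_pubmed("7000020"), cv_coip(),
                       host_organisms = list(human()))
  calms <- lapply(c("CALM1", "CALM2", "CALM3"), function(nm) {
    mif_interactor(nid(), cv_protein(),
                   names = mif_names(nm, sprintf("calmodulin (%s gene)", nm)),
                   organism = human())
  })
  kinase <- mif_interactor(nid(), cv_protein(),
                           names = mif_names("larch_kinase"),
                           organism = human())
  set <- mif_candidate_set(
    set_type = mif_cv("candidate set", mi_accession = "MI:1305"),
    candidates = lapply(calms, function(it) {
      mif_candidate(nid(), interactor_ref = it$id)
    })
  )
  ia <- mif_interaction(
    id = nid(), experiment_refs = ex$id,
    participants = list(
      mif_participant(nid(), mif_entity(candidate_set = set),
                      names = mif_names("calmodulin"),
                      experimental_roles = list(cv_prey())),
      mif_participant(nid(), mif_entity(interactor_ref = kinase$id),
                      experimental_roles = list(cv_bait()))),
    interaction_types = list(cv_assoc())
  )
  doc <- mif_document(mif_entry(experiments = list(ex),
                                interactors = c(calms, list(kinase)),
                                interactions = list(ia)))
  finish_case(doc, manifest(CANDIDATE_SET = 1L))
}

uc_j_stoichiometry <- function() {
  nid <- new_id_pool()
  sc <- uc_scaffold(nid, pmid = "7000021")
  ia <- binary_interaction(
    nid, sc,
    p1_args = list(stoichiometry = mif_stoich_mean(2, lexical = "2.0")),
    p2_args = list(stoichiometry = mif_stoich_range(2, 4,
                                                    min_lexical = "2",
                                                    max_lexical = "4")))
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(STOICHIOMETRY_ELEMENT = 2L))
}

uc_k_bibref_both <- function() {
  nid <- new_id_pool()
  bib <- mif_bibref(
    xref = mif_xref(mif_dbref("pubmed", "26919541")),
    attributes = list(
      mif_attribute("publication title",
                    "Interactome dynamics after viral infection"),
      mif_attribute("publication year", "2016"))
  )
  sc <- uc_scaffold(nid, bibref = bib)
  ia <- binary_interaction(nid, sc)
  doc <- mif_document(mif_entry(experiments = list(sc$experiment),
                                interactors = sc$interactors,
                                interactions = list(ia)))
  finish_case(doc, manifest(BIBREF_SPLIT = 1L))
}

#' Golden use-case fixtures
#'
#' Builds a small, validator-clean 3.0 document exercising exactly one use
#' case: (a) negative promoter feature range, (b) mutation resulting
#' sequence, (c) repeated feature detection methods, (d) feature role,
#' (e) feature-level kinetic parameters, (f) variable experimental
#' conditions (time course), (g) curated abstract complex, (h) cooperative
#' allosteric interaction, (i) calmodulin molecule set (CALM1/2/3),
#' (j) decimal stoichiometries, (k) bibref with both xref and attributes.
#' The expected-loss manifest of a 2.5 downgrade is attached as the
#' `"loss_manifest"` attribute (category -> count).
#'
#' @param case One of `"a"` .. `"k"`.
#' @return A [mif_document()] with a `loss_manifest` attribute.
#' @export
#' @examples
#' doc <- mif_use_case("i")
#' attr(doc, "loss_manifest")
mif_use_case <- function(case) {
  chk_string(case, "case")
  builder <- switch(case,
    a = uc_a_negative_range,
    b = uc_b_resulting_sequence,
    c = uc_c_multi_detection,
    d = uc_d_feature_role,
    e = uc_e_feature_parameters,
    f = uc_f_variable_parameters,
    g = uc_g_abstract_complex,
    h = uc_h_cooperative_allostery,
    i = uc_i_molecule_set,
    j = uc_j_stoichiometry,
    k = uc_k_bibref_both,
    mif_abort(sprintf("unknown use case '%s' (expected one of %s)", case,
                      paste(FIXTURE_CASES, collapse = ", ")))
  )
  builder()
}

#' @rdname mif_use_case
#' @export
mif_use_cases <- function() FIXTURE_CASES

# ---- random generator -------------------------------------------------------

GENERATOR_FLAGS <- c("neg_range", "resseq", "multi_detect", "feature_role",
                     "feature_params", "variable_params", "abstract",
                     "cooperative", "candidate_set", "stoich", "bibref_both")

#' Generator specification
#'
#' @param seed Integer seed; the same spec and seed always produce a
#'   byte-identical document.
#' @param n_entries Number of entries.
#' @param n_experiments,n_interactors,n_interactions Length-2 integer
#'   ranges sampled per entry.
#' @param flags Character subset of `neg_range`, `resseq`, `multi_detect`,
#'   `feature_role`, `feature_params`, `variable_params`, `abstract`,
#'   `cooperative`, `candidate_set`, `stoich`, `bibref_both`; every enabled
#'   flag is instantiated at least once.
#' @return An object of class `mif_generator_spec`.
#' @export
mif_generator_spec <- function(seed, n_entries = 1L,
                               n_experiments = c(1L, 2L),
                               n_interactors = c(3L, 6L),
                               n_interactions = c(1L, 3L),
                               flags = GENERATOR_FLAGS) {
  seed <- chk_id(seed, "seed")
  bad <- setdiff(flags, GENERATOR_FLAGS)
  if (length(bad)) {
    mif_abort(sprintf("unknown generator flag(s): %s",
                      paste(bad, collapse = ", ")))
  }
  rng <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) c(x, x) else x[1:2]
  }
  structure(list(seed = seed, n_entries = as.integer(n_entries),
                 n_experiments = rng(n_experiments),
                 n_interactors = rng(n_interactors),
                 n_interactions = rng(n_interactions),
                 flags = unique(flags)),
            class = "mif_generator_spec")
}

rint <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)
pick <- function(xs) if (length(xs) == 1L) xs[[1L]] else xs[[sample.int(length(xs), 1L)]]

random_feature <- function(nid, kind) {
  from <- rint(5L, 120L)
  switch(kind,
    plain = simple_feature(nid(), from = from, to = from + rint(0L, 30L)),
    neg_range = mif_feature(
      id = nid(), feature_type = mif_cv("binding site",
                                        mi_accession = "MI:0117"),
      ranges = list(mif_feature_range(cv_certain(),
                                      mif_pos_exact(-rint(500L, 3000L)),
                                      cv_certain(), mif_pos_exact(-1L)))),
    resseq = mif_feature(
      id = nid(), feature_type = mif_cv("mutation", mi_accession = "MI:0118"),
      ranges = list(mif_feature_range(
        cv_certain(), mif_pos_exact(from), cv_certain(), mif_pos_exact(from),
        resulting_sequence = mif_resulting_sequence(
          original = pick(c("K", "R", "A", "G")),
          new = pick(c("E", "Q", "W", "S")))))),
    multi_detect = simple_feature(
      nid(), from = from, to = from + 3L,
      detection_methods = list(
        mif_cv("identification by antibody", mi_accession = "MI:0421"),
        mif_cv("detection by mass spectrometry", mi_accession = "MI:0943"))),
    feature_role = simple_feature(
      nid(), type = mif_cv("observed-ptm", mi_accession = "MI:0925"),
      from = from, to = from,
      feature_role = mif_cv("prerequisite-ptm", mi_accession = "MI:0638")),
    feature_params = simple_feature(
      nid(), type = mif_cv("mutation", mi_accession = "MI:0118"),
      from = from, to = from,
      parameters = list(mif_parameter("kd", factor = rint(1L, 9L),
                                      exponent = -rint(3L, 9L),
                                      unit = "molar")))
  )
}

random_entry <- function(spec, nid) {
  flags <- spec$flags
  n_exp <- rint(spec$n_experiments[1L], spec$n_experiments[2L])
  n_int <- rint(spec$n_interactors[1L], spec$n_interactors[2L])
  n_ia <- rint(spec$n_interactions[1L], spec$n_interactions[2L])
  if (n_ia > 0L && (n_int == 0L || n_exp == 0L)) {
    mif_abort("infeasible spec: interactions need interactors and experiments",
              class = "psimif_spec")
  }
  if ("cooperative" %in% flags) n_ia <- max(n_ia, 1L)

  vv_ids <- integer(0)
  experiments <- lapply(seq_len(n_exp), function(k) {
    bib <- if (k == 1L && "bibref_both" %in% flags) {
      mif_bibref(xref = mif_xref(mif_dbref("pubmed",
                                           as.character(rint(100000L, 999999L)))),
                 attributes = list(mif_attribute("publication title",
                                                 paste(pick(WORDS), "study"))))
    } else {
      bib_pubmed(as.character(rint(100000L, 999999L)))
    }
    vps <- if (k == 1L && "variable_params" %in% flags) {
      list(mif_variable_parameter(
        description = "agonist concentration",
        unit = mif_cv("micromolar"),
        values = lapply(1:3, function(j) {
          id <- nid()
          vv_ids <<- c(vv_ids, id)
          mif_variable_value(id, value = as.character(10^j), order = j)
        })))
    } else {
      list()
    }
    mif_experiment(nid(), bib, pick(list(cv_two_hybrid(), cv_coip())),
                   host_organisms = list(human()),
                   variable_parameters = vps)
  })
  interactors <- lapply(seq_len(n_int), function(k) {
    mif_interactor(nid(), cv_protein(),
                   names = mif_names(sprintf("%s_%d", pick(WORDS), k)),
                   organism = human())
  })
  iref <- function() pick(interactors)$id
  mk_participant <- function(role, extra_feature = NULL, stoich = NULL,
                             candidate = FALSE) {
    if (candidate) {
      n_c <- rint(2L, 3L)
      idx <- sample.int(length(interactors), min(n_c, length(interactors)))
      set <- mif_candidate_set(
        set_type = mif_cv("candidate set", mi_accession = "MI:1305"),
        candidates = lapply(idx, function(i) {
          mif_candidate(nid(), interactor_ref = interactors[[i]]$id)
        }))
      return(mif_participant(nid(), mif_entity(candidate_set = set),
                             experimental_roles = list(role)))
    }
    mif_participant(
      nid(), mif_entity(interactor_ref = iref()),
      experimental_roles = list(role),
      features = if (is.null(extra_feature)) list() else list(extra_feature),
      stoichiometry = stoich %||% mif_stoich_unstated())
  }
  feature_flags <- intersect(flags, c("neg_range", "resseq", "multi_detect",
                                      "feature_role", "feature_params"))
  interactions <- lapply(seq_len(n_ia), function(k) {
    ex <- pick(experiments)
    n_p <- rint(2L, 4L)
    ps <- list(mk_participant(cv_bait()))
    for (j in seq_len(n_p - 1L)) {
      ps[[length(ps) + 1L]] <- mk_participant(cv_prey())
    }
    # instantiate feature-bearing flags on the first interaction
    if (k == 1L) {
      for (ff in feature_flags) {
        ps[[length(ps) + 1L]] <- mk_participant(
          cv_prey(), extra_feature = random_feature(nid, ff))
      }
      if ("stoich" %in% flags) {
        ps[[length(ps) + 1L]] <- mk_participant(
          cv_prey(), stoich = pick(list(
            mif_stoich_mean(rint(1L, 4L)),
            mif_stoich_range(1, rint(2L, 4L)))))
      }
      if ("candidate_set" %in% flags) {
        ps[[length(ps) + 1L]] <- mk_participant(cv_prey(), candidate = TRUE)
      }
    }
    mif_interaction(
      id = nid(), experiment_refs = ex$id, participants = ps,
      interaction_types = list(cv_assoc()),
      condition_sets = if (k == 1L && length(vv_ids) > 0L) {
        list(vv_ids[1L], vv_ids[-1L])
      } else {
        list()
      })
  })
  abstracts <- list()
  if (any(c("abstract", "cooperative") %in% flags)) {
    parts <- lapply(seq_len(min(2L, length(interactors))), function(i) {
      mif_participant(nid(), mif_entity(interactor_ref = interactors[[i]]$id))
    })
    effects <- list()
    if ("cooperative" %in% flags && length(interactions) > 0L) {
      effects <- list(mif_allostery(
        affected_refs = interactions[[1L]]$id,
        outcome = mif_cv("positive cooperative effect"),
        allosteric_molecule_ref = parts[[1L]]$id,
        effector = list(kind = "molecule",
                        ref = parts[[min(2L, length(parts))]]$id),
        evidence = list(list(
          bibref = bib_pubmed(as.character(rint(100000L, 999999L))),
          methods = list(mif_cv("inferred by author",
                                mi_accession = "MI:0363"))))))
    }
    abstracts <- list(mif_abstract_interaction(
      id = nid(), names = mif_names(paste0(pick(WORDS), "_complex")),
      interactor_type = cv_complex(), organism = human(),
      participants = parts, cooperative_effects = effects))
  }
  mif_entry(experiments = experiments, interactors = interactors,
            interactions = c(interactions, abstracts))
}

#' Generate a seeded random document
#'
#' Produces a validator-clean 3.0 document in which every enabled feature
#' flag is instantiated at least once.  Reproducible: the same spec (seed
#' included) yields a byte-identical serialization.  The caller's RNG
#' state is left untouched.
#'
#' @param spec A [mif_generator_spec()].
#' @return A [mif_document()].
#' @export
#' @examples
#' doc <- mif_generate(mif_generator_spec(seed = 42))
mif_generate <- function(spec) {
  if (!inherits(spec, "mif_generator_spec")) {
    mif_abort("`spec` must be a <mif_generator_spec>")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")
  nid <- new_id_pool()
  mif_document(lapply(seq_len(spec$n_entries), function(e) {
    random_entry(spec, nid)
  }))
}

#' Write all golden fixtures to a directory
#'
#' Serializes every use-case document (compact form) together with its
#' expected-loss manifest as JSON.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
mif_write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (case in FIXTURE_CASES) {
    doc <- mif_use_case(case)
    xml_path <- file.path(dir, sprintf("case-%s.xml", case))
    write_mif(doc, xml_path)
    man <- attr(doc, "loss_manifest")
    man_path <- file.path(dir, sprintf("case-%s.manifest.json", case))
    writeLines(as.character(jsonlite::toJSON(as.list(man),
                                             auto_unbox = TRUE,
                                             pretty = TRUE)),
               man_path)
    paths <- c(paths, xml_path, man_path)
  }
  invisible(paths)
}
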