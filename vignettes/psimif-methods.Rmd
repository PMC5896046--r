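---
title: "psimif: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{psimif: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psimif)
```

This vignette records how the package models the PSI-MI interchange
format, the design decisions taken where the format leaves room, the
numerical and procedural choices that affect results, and what the
synthetic fixtures do and do not demonstrate.

## The object model

A document (`mif_document`) is a list of entries at a declared level
(2.5 or 3.0). An entry owns experiments, interactors, an ordered list of
interactions (evidence and/or abstract), availabilities, a source and
free-text attributes.

**Single id namespace.** All ids within one entry — experiments,
interactors, interactions, participants, features, candidates, variable
values, availabilities — share one integer namespace, and every
reference must resolve inside the entry. The format does not mandate
separate per-type namespaces, and a single space matches long-standing
2.5 practice while making reference resolution a single lookup. Ids are
*non-semantic*: only the reference graph matters, which drives both
`mif_normalize()` (dense renumbering in document order) and
`mif_semantic_equal()` (ids never compared directly).

**Normal form.** The reader hoists inline experiment and interactor
definitions (extended-form documents) to the entry lists and keeps
references everywhere, so compact and extended serializations of the
same content parse to one in-memory graph. The writer re-inlines at
first use when asked for the extended form. A consequence: the order of
the entry-level definition lists is a serialization artifact (list order
in compact, first-use order in extended), so `mif_normalize()` sorts
experiments and interactors by a content key (labels, bibliographic
reference, detection method, taxon) rather than treating their order as
meaning. Attributes, secondary cross-references and interactor
candidates are likewise compared order-insensitively; everything else —
participants, ranges, detection methods, variable values, condition
sets — is order-sensitive.

**Coordinates.** Feature-range positions are 1-based inclusive on the
interactor sequence. Negative values are upstream (promoter-style)
coordinates; they are a 3.0-only capability since 2.5 positions are
unsigned. Position 0 is accepted by the model but flagged
(`POSITION_ZERO`, warning) because biological coordinate conventions
skip zero. `negative`, `intra_molecular` and `is_link` default to
`FALSE` when absent.

**Decimals.** Stoichiometries and parameter factors keep their lexical
form alongside the numeric value, so `value="2.0"` round-trips
byte-identically; semantic comparison uses the numeric value (tolerance
1e-9) and ignores the lexical mirror.

**Condition sets.** The format describes variable experimental
conditions on the experiment (`variableParameterList`) but does not
spell out how an individual interaction references the condition values
under which it was observed. This package models that link as a list of
sets of variable-value ids on the evidence interaction, serialized as
repeated `variableValueRefList` elements; an interaction with an empty
list is unconditioned. This is an implementation choice of this
package's dialect — it is what makes a time-course entry (three
interactions each tied to a distinct hours-post-infection value, as in
use case `f`) expressible and round-trippable. Whether `order` values
must be unique within a value list is likewise unstated: the model
permits duplicates and the validator warns (`ORDER_DUPLICATE`).

## Validation

`mif_validate()` emits findings from a closed, published list of 19
codes (`mif_finding_codes()`), in deterministic traversal order, never
raising. Profiles nest: `structural` (id uniqueness, reference closure,
required content, evidence-free abstract interactions), `semantic`
(content rules: resulting-sequence emptiness and IUPAC letters, inverted
certain ranges and stoichiometry ranges, non-negative stoichiometries
and orders, feature roles carrying an MI accession, coordinate
conventions), `cv` (accession format and known-accession checks).

Severity policy: violations of rules the format states are errors;
conventions it only implies are warnings — coordinate zero, negative
coordinates on a protein participant (negative positions exist for
genomic regions), duplicate `order` values, and mixing evidence and
abstract interactions in one interaction list (the format does not
forbid it, so the writer permits it and the validator warns). Any code
can be suppressed individually, which keeps every rule independently
testable.

The CV store is deliberately minimal: the accessions the package itself
emits plus their immediate parents, with `mif_load_cv()` merging a full
OBO file over it (file wins on label conflicts). No is-a reasoning is
attempted beyond the parent links present in the table; full ontology
closure is out of scope.

## Structural conformance without an XSD

The intended design bundles the public 3.0 XSD with a hand-written
structural check as the fallback when the schema file is unavailable;
this build ships the fallback. `mif_check_structure()` walks the element
tree against a rule table: allowed/required children, at-most-once
children, exclusive choices (a participant's entity, a range's position
forms), required attributes, and level restrictions — at 2.5 the
3.0-only elements are forbidden, positions must be unsigned, a feature
takes a single detection method and a `bibref` is an exclusive choice
between xref and attributes. The rule table covers exactly the dialect
the writer emits plus the tolerated variations the reader accepts, which
is the property the round-trip tests rely on.

## The 2.5 downgrade and its inverse

`mif_downgrade()` applies, per construct, the workaround 2.5 curators
actually used, and records one loss-report item per transformed
construct:

1. negative/zero positions → undetermined range statuses, positions
   removed;
2. resulting sequence → feature attribute (`original->new`) with the
   xref copied to the feature xref;
3. detection methods beyond the **first** → feature attributes. The
   first is kept because document order reflects curation priority; the
   observation that legacy parsers keep the *last* method they parse
   describes parser behaviour, not a serialization rule;
4. feature role → feature attribute;
5. feature parameters → the interaction parameter list, with a linking
   attribute naming the feature;
6. variable parameters and condition sets → experiment / interaction
   attributes;
7. an abstract interaction → a 2.5 interaction whose synthesized
   experiment has detection method "inferred by curator" (MI:0364); the
   abstract interaction's own xref doubles as the synthesized bibref
   when present, else an attribute-only bibref is used;
8. cooperative effects → interaction-level annotations;
9. a candidate set → one interactor typed by the set's CV term, the
   candidates exported as its xrefs (the Reactome-style molecule-set
   convention);
10. stoichiometry → a participant attribute;
11. a bibref holding both halves keeps its xref, the publication
    attributes moving to the experiment.

**Preservation convention.** Each transformed construct is additionally
stored verbatim, as an XML snippet of its 3.0 element, in an attribute
with a stable machine-parsable `psimi3:`-prefixed name. Reusing the
round-trip-tested serializer for the payloads is what makes
`mif_upgrade(promote = TRUE)` exact: promotion parses the snippet,
reinstates the construct, and removes the visible workaround (including
copied xrefs, moved parameters, synthesized experiments and placeholder
interactors once unreferenced). The Galois-style properties — promotion
inverts the downgrade up to `mif_semantic_equal()`, and
downgrade∘upgrade is the identity on 2.5 input with an empty loss
report — are property-tested on the golden fixtures and on random
documents. How IMEx databases name such annotation topics in the wild is
not standardized; the prefix is this package's convention.

## MITAB export

Only evidence interactions are tabulated — abstract interactions have no
experimental evidence to put in the experiment-derived columns, so they
are skipped with a logged notice. N-ary interactions expand under the
spoke model, hubbed on the bait participant (else the first in document
order); negative interactions are exported with column 36 set true.
Feature ranges serialize as `type:start-end` with `?` for unstated
positions. A candidate-set participant exports under the set's own
identity with the candidates in the alias column — MITAB defines no
mapping for molecule sets, so this is an implementation convention. Free
text is scrubbed of tabs, newlines and pipes; every row has exactly 42
columns.

## Fixtures and the random generator

`mif_use_case("a")` … `"k"` build the eleven golden documents, one per
use case (negative promoter range −2000..−1, mutation resulting
sequence, antibody+MS double detection, prerequisite-PTM role,
mutation-linked Kd with the wild-type value at the interaction level, an
hours-post-Sendai-infection time course with three interactions bound to
distinct time points, a curated abstract complex, an allosteric module
affecting an evidence interaction, the CALM1/2/3 calmodulin set, mean
and range stoichiometries, and a bibref holding both a PubMed xref and
title/year attributes). Each carries its expected-loss manifest, the
oracle for the conversion tests. Identifiers are invented except inert
echoes of published accessions; labels come from a fixed word list to
keep diffs reviewable.

`mif_generate()` produces seeded random documents (Mersenne-Twister,
caller's RNG state restored) in which every enabled feature flag is
instantiated at least once. Defaults — one entry, 1–2 experiments, 3–6
interactors, 1–3 interactions of 2–4 participants — keep documents at
the scale of a small curated entry. The generator aims at *structural
coverage*, not statistical realism: it makes no attempt at realistic
interaction-network topology, degree distributions, sequence content or
database accessions. Passing round-trip, validation, conversion and
export tests on generated documents therefore demonstrates that the
machinery is closed over the format's constructs, not that the package
has been exercised on the quirks of real database dumps (encoding
oddities, vendor dialects, very large files).

## Problem sizes and runtime choices

The round-trip suite runs 200 generated documents through both
serialization forms (400 cases); structural conformance is additionally
checked on all goldens and ten generated documents, and the conversion
and export properties on all goldens plus seeded samples. These sizes
were chosen to exercise every construct combination the generator can
produce while keeping the full suite comfortably fast on one CPU.
Documents are desk-scale; there is no streaming/SAX mode, and none is
needed at these sizes.

## Known limitations

* The embedded CV table is minimal; unknown accessions are only a
  warning, and hierarchy checks go no deeper than the stored parent
  links.
* MITAB is export-only; no MITAB parsing or matrix expansion.
* No MI-JSON, no web-service client, no ontology distribution.
* Non-strict reading drops dangling references from reference lists but
  keeps entity references (removing those would destroy the
  participant); `read_mif(keep_dangling = TRUE)` retains everything for
  later validation.
* The structural check validates this package's dialect of the grammar,
  not the full XSD; documents produced by other tools may use
  constructs the rule table does not know (they are reported as unknown
  elements rather than silently accepted).
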