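# psimif

An R toolkit for the HUPO-PSI molecular-interaction interchange format
(PSI-MI XML, "MIF"), levels 2.5 and 3.0, plus MITAB 2.7 tabular export.

## The problem this package addresses

Molecular-interaction databases exchange curated interaction data in the
PSI-MI XML format. Level 2.5 describes single-publication experimental
data well, but several kinds of information do not fit it:

* **Sequence features with signed coordinates** — e.g. a transcription
  factor binding a promoter region at positions −2000..−1 upstream of a
  gene. 2.5 positions are unsigned.
* **Mutation consequences** — the actual sequence change (`K -> R`) of a
  mutation feature, optionally cross-referenced to a SNP record
  (`resultingSequence`).
* **Multiply-detected features** — a PTM identified both by a specific
  antibody and by mass spectrometry (repeatable
  `featureDetectionMethod`), and **feature roles** such as
  prerequisite-PTM (MI:0638) or observed-PTM (MI:0925).
* **Mutation-linked kinetics** — Kd/k_on/k_off tied to a specific mutated
  feature rather than to the whole interaction (feature-level
  `parameterList`); wild-type values stay at the interaction level.
* **Dynamic interactomes** — interactions observed under varying
  experimental conditions, e.g. a time course of hours post-viral
  infection (`variableParameterList` on the experiment, with interactions
  referencing the condition values they were seen under).
* **Abstract (modelled) interactions** — evidence-free objects assembled
  from many publications: curated reference complexes, and **cooperative
  effects** (allostery and pre-assembly) one interaction exerts on
  another.
* **Molecule sets** — a participant that is one of several
  indistinguishable molecules, e.g. human calmodulin, an identical
  protein produced by the CALM1, CALM2 and CALM3 genes
  (`interactorCandidateList`).
* **Decimal stoichiometries** — a mean value or a `[min, max]` range per
  participant, and a `bibref` that holds *both* a PubMed xref and
  publication attributes.

Level 3.0 adds all of the above. This package implements the complete
3.0 object model in R, reads and writes both document forms (compact:
shared elements defined once and referenced; extended: related data
inlined at first use), validates documents semantically, converts
between 2.5 and 3.0 with a machine-readable loss report, and exports
evidence interactions to MITAB 2.7 (42 columns, spoke expansion of n-ary
interactions).

It is aimed at curators and tool developers who need to produce, check,
down-convert or tabulate MIF documents from R or from the shell.

## Core operations

* `read_mif()` / `write_mif()` — parse and serialize levels 2.5/3.0,
  compact or extended form, plain or gzipped; byte-deterministic output.
* `mif_normalize()` / `mif_semantic_equal()` — dense id renumbering and
  order-canonicalization; equality up to the format's semantics (ids are
  non-semantic, unordered lists compare order-insensitively).
* `mif_validate()` — a closed list of 19 finding codes across three
  profiles (`structural`, `semantic`, `cv`); `mif_check_structure()` —
  grammar conformance of the XML against its level.
* `mif_downgrade()` / `mif_upgrade()` — lossy, fully reported 3.0→2.5
  conversion using the documented 2.5 workarounds (e.g. an abstract
  complex becomes a 2.5 interaction whose synthesized experiment is
  "inferred by curator", MI:0364); upgrade with `promote = TRUE` restores
  every downgraded construct exactly.
* `write_mitab()` / `mif_expand_binary()` — MITAB 2.7 export with spoke
  expansion hubbed on the bait.
* `mif_use_case()` / `mif_generate()` — eleven golden fixture documents
  (one per supported use case, each with an expected-loss manifest) and a
  seeded random document generator.
* `mif_cli()` — `validate`, `convert`, `export`, `roundtrip`, `fixture`
  subcommands (wrapper script in `inst/cli/psimif.R`).

## Worked example: the calmodulin molecule set

```r
library(psimif)

doc <- mif_use_case("i")          # calmodulin CALM1/2/3 candidate set
doc
#> <PSI-MI 3.0 document: 1 entry>
#>   entry 1: 1 experiment(s), 4 interactor(s), 1 evidence + 0 abstract interaction(s)

mif_validate(doc, profile = "cv")
#> <no findings>

res <- mif_downgrade(doc)         # express it as level 2.5
res$report
#> <loss report: 1 item(s)>
#>   CANDIDATE_SET            1

# MITAB 2.7 row: set identity, candidates as aliases, set type column
strsplit(write_mitab(doc)[2], "\t")[[1]][c(1, 2, 5, 21)]
#> [1] "psimif:calmodulin"
#> [2] "psimif:larch_kinase"
#> [3] "psimif:CALM1(candidate)|psimif:CALM2(candidate)|psimif:CALM3(candidate)"
#> [4] "psi-mi:\"MI:1305\"(candidate set)"

# the downgrade is invertible: promote the 2.5 workarounds back to 3.0
mif_semantic_equal(mif_upgrade(res$document, promote = TRUE),
                   mif_normalize(doc))
#> <documents semantically equal>
```

The molecule set survives the 2.5 downgrade as a single molecule-set
interactor carrying the three candidates as cross-references, the loss
report records exactly one `CANDIDATE_SET` item, and promotion restores
the original candidate list.

From the shell:

```sh
Rscript inst/cli/psimif.R fixture --case i -o calm.xml
Rscript inst/cli/psimif.R validate calm.xml --profile cv
Rscript inst/cli/psimif.R convert calm.xml --to 2.5 -o calm25.xml --loss-report loss.json
Rscript inst/cli/psimif.R export calm.xml --format mitab27 -o calm.tsv
```

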