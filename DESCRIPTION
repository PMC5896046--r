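Package: psimif
Title: Read, Write, Validate and Convert PSI-MI XML Molecular Interaction Documents
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for the HUPO-PSI molecular interaction interchange
    format (MIF). Provides a complete object model for PSI-MI XML level 3.0
    including sequence-feature resulting sequences, negative feature-range
    coordinates, repeatable feature detection methods, feature roles and
    feature-level kinetic parameters, variable experimental conditions
    (dynamic interactions), abstract (modelled) interactions with
    cooperative effects (allostery and pre-assembly), interactor candidate
    sets (molecule sets) and decimal stoichiometries.  Reads and writes both
    the compact and the extended document forms, validates documents
    semantically against a closed rule set and an embedded minimal
    controlled-vocabulary store (extensible from OBO files), performs a
    documented lossy downgrade to level 2.5 with a machine-readable loss
    report and a promoting upgrade back to 3.0, exports evidence
    interactions to MITAB 2.7 with spoke expansion, and generates
    deterministic fixture documents for every supported use case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
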