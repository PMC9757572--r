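Package: readbridge
Title: Curation and Cross-Mapping of UK Primary-Care Read Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for harmonising coded UK primary-care (GP) clinical
    events. Maps Read v2 and CTV3 (Read v3) codes to ICD-10/ICD-10-CM via
    lookup tables, bridges ICD-9-only mappings to ICD-10, and fuzzy-matches
    unmapped disease terms with a pre-indexed character-trigram search.
    Refines one-to-many lookup mappings using TRUD-style mapping-status,
    refine and add-code flags; cross-maps Read codes to ICD-10 through
    SNOMED CT-style concept tables with inactive-concept resolution and
    broad/narrow selection policies. Includes a mapping-quality audit
    framework (quality categories, auto-vs-manual agreement classes,
    flat-prior Bayesian credible intervals for proportions), a
    prevalence-inflation diagnostic for erroneous one-to-many mappings,
    and seeded synthetic-fixture generators so every stage is testable
    without access-restricted source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
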