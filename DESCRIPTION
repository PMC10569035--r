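Package: tpcurate
Title: Headless Curation of Text-Mined Transformation-Product Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit that turns text-mined chemical-name
    annotations (PubChem PUG-View-style markup spans linked to compound
    identifiers) into validated, deduplicated transformation-product (TP)
    reaction libraries and suspect lists. Provides parsing of annotation
    JSON into candidate-reaction tables, curator decision application,
    reaction validation (salts, stereo-only differences), CID-pair
    deduplication against an existing transformations library, library
    merging, suspect-list export, TP labeling of identified compounds,
    parent-TP pair linkage, and paired XlogP distribution comparison.
    Structure handling (canonical SMILES, InChIKey, formula, monoisotopic
    mass) is backed by OpenBabel. Deterministic fixture generators with
    planted ground truth make every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    ChemmineOB,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
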