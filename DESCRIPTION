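Package: refgap
Title: Gap Analysis and Quality Auditing of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing DNA barcode reference libraries of the kind
    held in the Barcode of Life Data System (BOLD). Provides record-level
    curation (marker, sequence-length, ambiguity and BIN filters; duplicate
    collapse; explicit exclusions), reconciliation of conflicting taxonomic
    identifications within Barcode Index Number (BIN) clusters, assignment of
    BINs to environmental realms (marine, freshwater, terrestrial),
    species-level barcode quality grading (A-E, after the BAGS scheme),
    checklist-based family and species coverage statistics, and geographic
    completeness summaries. A synthetic-library generator with fully known
    ground truth makes every pipeline stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
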