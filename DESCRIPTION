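Package: worknarr
Title: Text Interrogation Methods for Work-Related Injury Surveillance in
    Emergency Department Narratives
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies potentially work-related injury cases from short
    free-text triage narratives recorded at emergency department
    presentation. Implements and compares three interrogation approaches:
    a simple keyword search on "work", an index search driven by a curated
    list of minimal work-related word stems built from a manually annotated
    review sample, and a tag-supervised concept classifier that learns
    term/concept associations with the coded activity groups and classifies
    cases by relevance-score differences with an adjustable cutoff. Includes
    a full sensitivity/specificity/PPV evaluation layer, cross-method
    overlap counts, and a calibrated synthetic narrative generator so the
    whole pipeline runs end-to-end on simulated surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
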