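Package: ccfo
Title: Cardiac-Centered Frailty Ontology Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Executable toolkit around the Cardiac-centered Frailty Ontology
    (CCFO): an ontology data model with concept hierarchy, indicator-term
    lexicon, qualifier values and per-concept Rockwood frailty scores;
    lexicon-based extraction of frailty findings (with qualifier, course and
    assertion resolution) from clinical free text; rule-based computation of
    Barthel index, Katz ADL and SF-36 scores from extracted findings;
    threshold-based interpretation of ten frailty instruments; group-wise
    maximum aggregation of findings into a patient-level frailty profile; and
    a seeded generator of synthetic clinical-note snippets with gold-standard
    annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
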