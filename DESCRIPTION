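Package: relrate
Title: Collect and Pool Expert Relevance Ratings of De-Identified Medical Record Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building expert relevance-rating studies over electronic
    medical record (EMR) items. Generates seeded synthetic patient records with a
    ground-truth manifest of planted protected health information (PHI); selects
    record items inside a +/- 2-year window around an index radiology exam;
    rule-redacts names, dates and identifying numbers, reduces demographics to
    sex and capped age, and emits de-identified scenario XML documents; manages
    the rating workflow (raters, scenario-family assignments, next-item
    auto-advance on a 4-step relevance scale, progress tracking, ratings export
    as XML); and pools per-item ratings across raters into summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
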