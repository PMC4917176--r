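Package: resmine
Title: Mining Database and Software Mentions from the Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dictionary and rule-based recogniser for database and software
    (resource) name mentions in full-text biomedical articles, with a
    rule-feature machine-learning filter for false positives, document
    section zoning, and the survey analytics built on the extracted
    mentions: top-N usage tables, journal proportions, temporal relative
    usage with random-walk significance envelopes, year-over-year change
    scores, persistence runs, long-tail summaries, and sparse SVD
    clustering of journals and resources. Includes a synthetic corpus
    generator with gold standoff annotations so every stage of the
    pipeline can be evaluated against known ground truth, and strict and
    lenient span-matching evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    Matrix,
    randomForest,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
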