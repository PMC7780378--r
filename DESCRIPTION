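Package: pdvoice
Title: Social-Listening Share-of-Voice Analysis of Parkinson's Disease
    Symptom Dialogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dictionary-based mining of patient dialogue corpora
    about Parkinson's disease. Normalizes noisy token streams with a bigram
    noisy-channel typo corrector and paired double-negation cancellation,
    tags symptom and graded negative-sentiment mentions from lexicons with
    nocturnal-context detection, and computes share of voice (SOV),
    compounded annual growth rates (CAGR), weighted negative-sentiment
    scores, and two-proportion trend and between-group tests. Ships a
    synthetic dialogue-corpus generator with ground-truth annotations so
    the full pipeline is testable without access to the original crawled
    dialogues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
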