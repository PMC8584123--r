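Package: coexpose
Title: Factorial Co-Exposure Transcriptomics and Endpoint Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for 2x2 factorial exposure studies
    (chemical x physical agent) in reproductive toxicology. Implements
    per-gene factorial linear models with empirical-Bayes variance
    moderation suited to very small replicate numbers, contrast testing
    against control, DEG filtering and overlap summaries; classification
    of combined-exposure effects into additivity, potentiation,
    antagonism or unexpected responses via an interaction ratio on log2
    fold changes; a random-sampling gene-set median-shift test; and
    statistics for histology and behavior endpoints (Abercrombie-corrected
    stereological counts, two-way ANOVA with Tukey HSD and compact letter
    display, partner-preference scores). A seeded synthetic-data generator
    with planted ground truth makes the whole pipeline verifiable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    limma,
    multcomp
Config/testthat/edition: 3
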