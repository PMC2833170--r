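Package: crthedges
Title: Search Filters for Cluster Randomized Trials in MEDLINE-Style Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating electronic search filters
    (hedges) that retrieve reports of cluster randomized trials from
    bibliographic databases. Provides a reader and writer for MEDLINE
    tagged-format citation files, an executable engine for the Ovid-style
    numbered-line query dialect (Boolean operators, adjacency, truncation,
    textword, publication-type and MeSH heading searches), the canonical
    published filters as named built-ins, diagnostic-accuracy metrics for
    retrieval (sensitivity, precision, fall-out, number needed to read,
    relative recall), reporting-trend statistics, a title/abstract
    identifiability classifier, a seeded synthetic corpus generator with
    gold-standard labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
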