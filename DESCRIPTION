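Package: grnoverlap
Title: Overlap Validation of Gene Regulatory Network Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates predicted transcription-factor target sets from a
    weighted gene regulatory network (such as a GENIE3 ranking) against
    independent differential-expression evidence. Implements the shared-ratio
    overlap statistic between gene sets, resampling null distributions with an
    exact binomial sign test, a candidate-regulator scan with senescence
    fold-change annotation, and polyploidy-aware analyses of homeolog triads
    (pairwise homeolog overlap, expression-movement categories, genome-of-origin
    association). Ships a synthetic-data generator that plants recoverable
    overlap structure so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
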