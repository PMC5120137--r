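Package: txcell
Title: Absolute Transcript Quantification with Internal RNA Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative (transcripts-per-cell) bacterial
    transcriptomics calibrated with internal RNA spike-in standards.
    Implements the recovery regression and reads-per-copy conversion for
    spiked sequencing libraries, absolute per-cell abundance tables and
    their distribution summaries, growth-rate and growth-phase analysis of
    cell-density time series, a methanol carbon-budget yield model for
    methylotrophic growth, differential-abundance calling (one-way ANOVA,
    Benjamini-Hochberg correction, pooled pairwise t tests and a minimum
    fold-change rule), Pearson-correlation complete-linkage sample
    clustering, and a synthetic-data generator that emulates the
    statistical structure of spiked libraries from a streamlined marine
    methylotroph so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
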