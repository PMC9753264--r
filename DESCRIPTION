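Package: strobemap
Title: Short-Read Mapping and Alignment with Syncmer-Anchored Randstrobe Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-and-extend short-read mapper built on fuzzy, variable-length
    seeds: canonical open syncmers linked into randstrobes with a skewed,
    bit-count sampling function. Provides reference indexing with abundance
    masking, merged-match candidate detection, MAPQ scoring, single- and
    paired-end base-level alignment with rescue modes, SAM and PAF-like
    output, the E-hits seed-repetitiveness statistic, and a synthetic-data
    generator with truth-based accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
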