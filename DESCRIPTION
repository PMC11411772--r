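Package: svconsensus
Title: Length-Binned Consensus Calling and Benchmarking of Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A consensus framework for short-read structural variant (SV)
    discovery. Call sets from multiple upstream SV callers are benchmarked
    against a gold-standard truth set using breakpoint-resolution matching
    at a configurable tolerance (tau), stratified by variant length bin.
    The top-performing caller per length bin is recorded in a trained
    profile, and discovery mode merges the winning callers' calls into a
    single deduplicated consensus VCF, with additional precision- and
    recall-optimized modes. Includes a read-pair-aware alignment
    downsampler that never strands mates, and a synthetic call-set
    generator with controlled per-bin sensitivity, false-positive rate and
    breakpoint jitter for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    Rsamtools,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
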