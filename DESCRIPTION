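Package: spliceguide
Title: Filtered Two-Pass Spliced Alignment Guidance for Long RNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts splice junctions and alignment-quality metrics from
    first-pass spliced alignments of high-error long RNA reads (nanopore
    direct RNA sequencing), classifies junctions as genuine or spurious
    using rule trees over junction alignment distance (JAD), read support,
    primary donor/acceptor status and intron motif, augments the rules with
    cross-validated logistic-regression models of splice-site sequence, and
    writes a filtered guide-junction BED for a second alignment pass. Also
    provides an annotation-aided filtering cascade built on randomized
    forests, a direct-RNA read simulator with homopolymer and Markov-chain
    basecall error models, intron-chain based alignment evaluation, and a
    synthetic fixture generator so the whole workflow can be exercised on
    self-contained data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    ranger,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
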