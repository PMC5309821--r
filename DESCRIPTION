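Package: enhins
Title: Enhancer-Associated Small Insertion Discovery from ChIP-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers small (1-31 bp) insertions in enhancer DNA from
    H3K27ac ChIP-seq reads. Reads that fail gapless alignment are rescued
    with an insertion-aware gapped aligner, both directly and after greedy
    overlap assembly into contigs; candidate insertions are verified by an
    exhaustive zero-mismatch realignment, keyed as left-normalized
    coordinate+allele identifiers, deprioritized when they match dbSNP keys
    or recur across many samples, scored for allele-specific ChIP-seq
    coverage bias against per-variant mini-genomes, and assigned to genes
    sharing a CTCF/cohesin insulated neighbourhood, with a permutation test
    for oncogene enrichment. Includes an amplicon-sequencing confirmation
    caller and a synthetic-data generator that plants insertions with
    configurable zygosity and depth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    withr,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
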