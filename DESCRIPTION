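Package: kmerscreen
Title: Targeted k-mer Screening of RNA-seq Reads for Clinically Relevant Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free detection of known gene fusions, single nucleotide
    variants, intragenic-deletion transcript isoforms and expression markers
    (DUX4-type) directly from raw RNA-seq reads. Reads are decomposed into a
    k-mer count table (k = 31 by default); k-mers are then assembled across
    short curated target sequences, identifying the reference path and
    divergent paths indicative of substitutions, insertions or deletions.
    Includes builders that construct all five target families from a genome
    FASTA and GTF annotation, coverage-based reporting filters producing a
    single per-sample variant report, and a seeded read simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stringi,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
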