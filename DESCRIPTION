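Package: spinmap
Title: Mapping piggyBac Transposon Integration Sites from Splinkerette-PCR Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for locating piggyBac transposon
    integration sites in a genome from splinkerette-PCR (spPCR) junction
    sequencing reads. Covers nested-primer and adapter trimming with flank
    (5'TR/3'TR) assignment, ungapped end-to-end alignment (built-in
    seed-and-extend aligner or SAM import), detection of junction reads whose
    genome-facing terminus is the duplicated TTAA target site, two-stage
    candidate filtering (support on both flanks, no internal TTAA), and
    classification of validated sites against a GFF3 gene annotation into
    exon, UTR, intron or intergenic categories. A synthetic-data module
    generates toy genomes, ground-truth TTAA insertions and splinkerette-style
    paired FASTQ reads with configurable error and background so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
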