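Package: intronPAS
Title: Intronic Polyadenylation Signals, Nested Genes and
    Intron-Terminated Isoforms
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of cryptic polyadenylation signals (PAS)
    inside introns. Classifies annotated introns into three categories
    (PAS present, PAS not found, sequence too short) with a configurable
    hexamer-weight scanner; discovers host/nested gene architectures by
    strict interval containment of one gene inside another gene's intron;
    catalogs genes with a transcript isoform terminating within an intron
    of a spliced isoform and applies boundary-overlap and two-form
    exclusion filters; quantifies the spliced and intron-terminated
    isoforms per RNA-seq sample from read-density differences and their
    ratio; and sorts genes into expression groups with a heat-map matrix
    across samples. Includes a deterministic simulator emitting GFF3,
    FASTA and SAM with full ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), GenomicRanges
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    grid,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
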