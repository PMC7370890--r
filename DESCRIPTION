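Package: psiphase
Title: Exon-Level PSI and Cassette-Exon Phasing from Full-Length Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative splicing of large, repetitive genes from
    aligned long-read (Iso-Seq) consensus reads. Collapses a gene annotation
    into disjoint exonic parts (one metatranscript per gene), discovers
    unannotated exons from spliced alignments, computes full-length-read
    weighted percent-spliced-in (PSI) per exonic part per sample, and phases
    sets of cassette exons within single reads to identify and quantify
    transcript structures against known annotations. Includes a deterministic
    synthetic-data generator (toy genome, GTF, aligned SAM reads with
    full-length multiplicities, internal oligo(dT) priming truncation) so the
    whole pipeline is testable without sequencing data, and a command-line
    interface binding the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    GenomicAlignments,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
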