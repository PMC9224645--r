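Package: genevista
Title: Phenotype-Driven Gene-Panel Variant Triage and Read-Evidence Browsing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters, classifies and summarizes a patient's genetic variants
    over a phenotype-derived gene panel, and renders exon-level and
    single-base-resolution views of the supporting read alignments. Reads
    VCF variant calls, SAM/BAM alignments, UCSC refFlat gene models,
    HPO-style phenotype-to-gene tables and dbSNP-subset catalogs; annotates
    variants as known or novel, computes per-gene summaries, projects reads
    to reference coordinates through their CIGAR strings, indexes them into
    overlapping genomic partitions for fast windowed retrieval, builds
    pileups, and calls zygosity from per-variant supporting-read fractions.
    A seeded synthetic-fixture generator produces complete miniature test
    worlds (reference contig, gene models, reads with spiked variants at
    controlled allele fractions, and the matching VCF) so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
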