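Package: paralocus
Title: Dissecting Tandem-Duplicated Gene Loci from Sanger-Scale Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resolving a tandem-duplicated cytochrome P450 gene
    locus (the equine CYP2D50 region, orthologous to human CYP2D6) from
    gene-local Sanger-style data: self-similarity scanning to split a fused
    gene annotation into two paralogs, exon- and gene-level identity tables,
    diploid IUPAC-consensus variant calling with codon-level effect
    annotation and cohort allele frequencies, transcript-to-paralog
    assignment by genotype-pattern replication, gene-conversion hybrid
    allele detection with breakpoint-interval localization, SIFT/PROVEAN
    threshold classification, and relative standard curve qPCR
    quantification. A seeded synthetic-data generator produces every input
    the pipeline consumes, with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
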