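Package: dupcodon
Title: Selection on Synonymous Sites and Codon Usage in Duplicate Genes
    Encoding Identical Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-evolution toolkit for pairs of duplicate genes that
    encode the same protein, modelled on the histone variant H3.3 and its two
    vertebrate genes. Provides codon-aware alignment of identical-protein
    coding sequences, raw nucleotide substitution scores, absolutely conserved
    third-position and fourfold-degenerate site frequencies and their
    between-paralog ratios, GC3, two codon-usage metrics (raw and
    amino-acid-specific frequencies) with correlation benchmarking against
    transcriptional-program and genome-wide profiles, gap-excluded 3'UTR
    identity, a quantitative synteny scan over gene neighborhoods, and a
    seeded synthetic-data generator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
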