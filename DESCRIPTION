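Package: numtatlas
Title: Detection, Classification and Genomic-Context Analysis of Nuclear
    Mitochondrial DNA Sequences (NUMTs)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering nuclear mitochondrial DNA sequences
    (NUMTs) in assembled genomes and for dissecting their post-insertion
    history. Provides a seed-and-extend local aligner with Karlin-Altschul
    E-values (plus a BLAST outfmt-6 reader), classification of NUMTs into
    insertion-type and duplicate-type copies via flanking-DNA homology,
    reconstruction of complex NUMT clusters fragmented by transposable
    elements, genomic-context profiling (AT content of flanks,
    intergenic/intronic/coding assignment, NUMT and TE density tracks,
    TE vicinity), comparative statistics (phylogenetic generalized least
    squares under Brownian motion, Spearman correlation, exact Wilcoxon
    rank tests), and a synthetic-genome simulator that plants NUMTs, genes
    and transposable elements with a known truth table so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
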