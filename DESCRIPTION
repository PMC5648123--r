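Package: immunoMotifs
Title: Immune-Modulatory DNA Motif Profiling of Gut Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-metagenomics toolkit for profiling immune-modulatory
    DNA motifs (immunostimulatory CpG motifs and the immunosuppressive TTAGGG
    and TCAAGCTTGA motifs) in shotgun metagenomes. Provides quality trimming
    and host-read filtering of reads, exact both-strand motif scanning with
    reverse-complement-palindrome deduplication, per-dataset motif occurrence
    statistics, best-hit taxonomic attribution of motif-bearing reads,
    read-recruitment coverage normalized to a fixed dataset size, taxon and
    functional-category relative-abundance profiles, Shannon/Chao1/rarefaction
    diversity estimation, a Metastats-style nonparametric permutation test with
    a Fisher's exact path for sparse features, genome-bin screening and
    decontamination against reference identities, and a ground-truthed
    synthetic-community simulator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Sequencing, StatisticalMethod
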