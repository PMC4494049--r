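Package: saurannot
Title: Iterative Homology Annotation of De Novo Transcriptome and Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Homology-based annotation of de novo transcriptome assemblies
    by iterative similarity searches against ordered reference databases
    (mitochondrial, non-coding RNA, coding cDNA, taxon mRNA), with
    reciprocal-best-hit quality control, anchored majority-rule consensus
    building, an exon-projection genome annotator, and completeness
    assessment against conserved gene sets. Includes a built-in seeded
    local aligner (nucleotide and six-frame translated), CD-HIT-style
    greedy redundancy clustering, and deterministic synthetic-data
    generators with ground-truth tables for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    stringi,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
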