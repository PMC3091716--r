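Package: crmminer
Title: Cis-Regulatory Module and Motif Module Discovery from Orthologous
    Non-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts cis-regulatory modules (CRMs) and recurrent motif
    combinations (motif modules) in the non-coding sequences of orthologous
    mammalian genes. Conserved blocks are selected by discontiguous sequence
    similarity computed from seed-and-extend local alignments, conserved
    segments are scanned with position weight matrices whose score cutoffs
    are calibrated on random background sequence, recurrent motif
    combinations are mined with an FP-tree and scored with a Poisson clump
    approximation, and downstream statistics characterise target genes,
    gene-set overlap, and order, distance, strand and location preferences
    of the predicted modules. A seeded synthetic-data generator produces
    orthologous gene groups with planted CRMs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
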