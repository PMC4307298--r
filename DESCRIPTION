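Package: srnascreen
Title: Small RNA-Seq Knockdown Screen: Simulation, Pair-HMM Mapping and
    Exact Negative-Binomial Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a barcoded
    small-RNA deep-sequencing screen comparing a knockdown library against a
    control library without biological replicates. Provides a synthetic-data
    generator (toy genome, miRNA/tRNA/rRNA annotation, negative-binomial
    per-feature counts, adaptored and barcoded FASTQ reads with
    position-dependent sequencing error), barcode demultiplexing and adaptor
    trimming with the screen's abundance and length filters, a pair hidden
    Markov model read mapper with iterative per-cycle error-profile
    estimation and Phred-scaled mapping qualities, strand-aware feature
    quantification, and an exact conditional negative-binomial two-group
    test with common dispersion estimated by treating the two libraries as
    pseudo-replicates, Benjamini-Hochberg adjustment and FDR calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
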