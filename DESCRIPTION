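Package: topicgrn
Title: Topic Models, Gene Regulatory Networks and In Silico Transcription
    Factor Knockouts for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links grade-of-membership topic models of single-cell RNA-seq
    counts to gene-regulatory-network (GRN) architecture and in silico
    transcription-factor knockout simulations. Fits multinomial topic models
    by Poisson non-negative matrix factorization, constructs context-specific
    GRNs by bagged ridge regression of KNN-imputed expression restricted to a
    motif-derived base GRN, computes eigenvector centralities, and scores
    each transcription-factor knockout by projecting the propagated
    expression shift onto a two-dimensional embedding and taking dot
    products with topic-loading gradient fields. Includes a synthetic-data
    generator with planted ground truth (topics, signed regulatory edges,
    population-specific network density, motif instances near gene
    transcription start sites) so the whole inference chain can be
    benchmarked end to end, plus a PWM scanner, peak-to-TSS window
    assignment, and hypergeometric gene-set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
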