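Package: plastidcompat
Title: Candidate-Gene Screening for Plastid-Nuclear Incompatibility in Pea
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing nuclear-cytoplasmic conflict in crosses of
    wild and cultivated peas (Pisum sativum) from whole-plastome comparison
    down to candidate incompatibility genes. Implements pairwise plastome
    variant calling and coding-effect classification under the plastid
    genetic code, a phenotype-pattern candidate funnel, derived-protein
    reconstruction with alternative-start and stop-readthrough handling,
    variable-position tabulation and exclusive-difference filtering of
    protein alignments, tandem-repeat and motif annotation, syntenic
    gene-interval filtering for nuclear counterparts of plastid loci,
    a minimal recombinant-inbred-line linkage toolkit with the
    Haldane-Waddington correction, and a primary/secondary determinant
    rule engine that predicts cross compatibility and infers determinant
    states from observed crosses by exhaustive constraint satisfaction.
    Seeded synthetic-data generators produce every input the pipeline
    consumes, with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
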