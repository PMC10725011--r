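Package: tnseqdiv
Title: Comparative Transposon Insertion Sequencing Analysis via Effective
    Insertion Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies conditionally important genes from comparative
    transposon insertion sequencing (TnSeq) experiments. Per-gene transposon
    insertion diversity is summarized as an effective density: the
    exponentiated Shannon index of per-site read-count proportions (the Hill
    number of order one, i.e. the effective number of equally abundant
    insertion sites) divided by gene length. Genes whose effective density
    differs between two growth conditions are called by three complementary
    statistics: log2 fold change of condition-mean effective density, Cook's
    distance outliers of a between-condition regression, and Welch's t-test
    across replicates, with consensus reporting across methods. Includes
    readers for insertion-site tables (TSV and wig), GFF3 and flat-file gene
    annotations, replicate quality-control filtering, median-of-ratios count
    normalization, COG functional-category tallies, replicate-subset
    sensitivity reruns, and a seeded synthetic-experiment generator with
    known per-gene fitness effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
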