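Package: poolAssoc
Title: Pool-Seq Contingency Chi-Square Association Mapping with Gene-Wise
    Score Aggregation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Association mapping from pooled resequencing (pool-seq) of
    phenotypically contrasted insect pools. Computes per-SNP contingency
    chi-square tests on nucleotide read counts between resistant and
    susceptible pools, aggregates SNP -log10(p) values into gene-wise
    "mean of top 5 percent" scores, applies Benjamini-Hochberg FDR and a
    score cutoff to define high-association gene sets, intersects the sets
    across independent collections, extracts the extreme top-decile subset,
    and tests functional categories for hypergeometric over-representation
    against the coding-gene background. Includes a seeded synthetic
    pooled-read-count generator with planted resistance loci for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Genetics, SNP, Sequencing, GeneSetEnrichment, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
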