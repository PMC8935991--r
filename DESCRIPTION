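Package: BSAscan
Title: Bulked-Segregant Analysis from Multi-Sample VCFs (SNP-Index,
    Delta SNP-Index, Simulation-Based Confidence Intervals)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical core for bulked-segregant analysis of diploid
    biparental crosses in the MutMap / QTL-seq style. Reads a
    multi-sample VCF (one parent, one or two phenotype-selected bulks),
    filters variants on mapping quality, strand bias, depth and parental
    genotype, computes the SNP-index (fraction of reads carrying the
    non-parental allele) and the delta SNP-index between two bulks,
    derives depth-dependent confidence intervals by Monte-Carlo
    simulation of bulk composition and read sampling under the null of
    no linkage, calls candidate loci, summarises results in sliding
    windows and genome-scan plots, and includes a synthetic-data
    generator that plants a causal locus with Haldane linkage decay so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
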