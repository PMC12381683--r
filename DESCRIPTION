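Package: cnvselscan
Title: Selection-Signature Scanning of Deletion Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-level analysis of deletion copy-number variants (CNVs)
    between two trait-divergent groups of diploid individuals: merging of
    per-individual structural-variant calls by reciprocal overlap and genotype
    concordance, quality control with an exact excess-heterozygosity test,
    sliding-window Weir-Cockerham FST and per-group nucleotide diversity with
    a log2 diversity-ratio contrast, top-quantile dual-criterion selection of
    candidate loci, gene and genomic-feature annotation, and cohort
    distribution statistics. Includes a Balding-Nichols style simulator of
    genotyped deletion-CNV cohorts with controllable differentiation,
    missingness and planted selective sweeps, so the whole pipeline is
    testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics,
    jsonlite,
    BiocGenerics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
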