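Package: gbspop
Title: GBS Locus Delineation, SNP Filtering, Outlier Detection, and
    Population Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A post-alignment population-genomics toolkit for
    genotyping-by-sequencing (GBS) data. Delineates GBS loci from mapped
    read positions with depth-based missing-data flagging and library QC,
    applies a SNP filter cascade (call rate, depth excess, Hardy-Weinberg
    exact test with heterozygote-excess removal, minor allele frequency)
    with per-step accounting, detects outlier SNPs with a PCA/Mahalanobis
    scan and a trimmed chi-square FST scan combined into a consensus
    neutral panel, and computes population-structure statistics:
    rarefied allelic richness and heterozygosity, Nei's genetic distance,
    distance-based AMOVA with permutation tests, pairwise multi-locus
    Weir-Cockerham theta with bootstrap confidence intervals, and
    discriminant analysis of principal components (DAPC) with individual
    assignment. Includes a Balding-Nichols island-model genotype simulator
    and a mapped-read stack simulator for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    MASS,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
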