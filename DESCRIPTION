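Package: sweepscanr
Title: Windowed Selective-Sweep Scans with FST, Pi-Ratios and XP-EHH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects selective sweeps from phased biallelic SNP data by scanning
    10-kb windows for joint empirical outliers of the Weir-Cockerham fixation
    index (FST), nucleotide-diversity ratios (pi-ratio), and cross-population
    extended haplotype homozygosity (XP-EHH); merges outlier windows into sweep
    regions, annotates overlapping genes, extracts highly differentiated missense
    SNPs, and intersects swept genes with differentially expressed genes at a
    Benjamini-Hochberg FDR cutoff. Ships a forward Wright-Fisher simulator (three
    populations from a common ancestor, one carrying a hard sweep) and a
    negative-binomial count simulator so the whole pipeline can be exercised and
    calibrated on synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    DESeq2,
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
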