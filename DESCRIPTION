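Package: sweepscan
Title: Selection-Signature Scans from Phased Variants with Windowed
    FST/Diversity Cross Analysis, iHS and xpEHH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects signatures of positive selection in structured
    populations from phased biallelic SNP data. Implements windowed
    Weir-Cockerham FST and Nei-Li nucleotide diversity with the
    log2 diversity-ratio cross analysis (joint 5 percent right tails,
    Mann-Whitney validation), within-population iHS and cross-population
    xpEHH haplotype scans with windowed outlier calling, candidate-region
    assembly with gene/QTL interval annotation and gene-list
    intersection, pairwise FST with bootstrap p-values, LD-decay
    profiles and greedy LD pruning. A forward-time Wright-Fisher
    simulator with divergence, bottlenecks and hard sweeps provides
    ground-truth data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
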