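Package: divscan
Title: Immune Gene-Set Divergence Scans for Structured Mosquito Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic divergence analysis of candidate gene sets
    among closely related taxa, built around the Anopheles gambiae complex
    use case: functional classification of coding SNPs by amino-acid change
    or 2-fold codon-usage shifts, per-locus heterozygosity and chi-square
    genotype-taxon association, Weir-Cockerham F_ST variance components with
    ratio-of-sums multilocus estimates, EM maximum-likelihood two-locus
    haplotype frequencies and r2 linkage disequilibrium from unphased
    genotypes, gene-set bootstrap and inversion-overlap permutation tests,
    and an FDIST-style F_ST outlier scan against a hierarchical-island
    structured-coalescent null. A Balding-Nichols synthetic-data generator
    reproduces the statistical structure of the study design so every stage
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
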