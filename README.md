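# divscan

Population-genetic divergence scans for candidate gene sets among closely
related taxa, built around the *Anopheles gambiae* complex use case: three
sympatric taxa (*A. coluzzii* and the Bamako and Savanna forms of
*A. gambiae* s.s.) whose innate-immunity genes may diverge as adaptations
to different larval habitats — and thereby shape both malaria transmission
and incipient speciation.

Given genotypes (VCF or tabular), gene/inversion annotations (BED) and an
immune gene list, the package answers three questions:

1. **Is the candidate gene set more diverged than the genome background?**
   Multilocus Weir–Cockerham F_ST — variance components *a*, *b*, *c* and
   the ratio-of-sums estimator θ̂ = Σa / Σ(a+b+c) — of the immune set is
   compared against B random equal-sized non-immune gene sets
   (add-one empirical p = (1 + #{null ≥ obs})/(B + 1)), with genes the
   resampling unit so within-gene LD is preserved. Companion tests cover
   SNP counts per gene set and the permutation test for immune-gene
   clustering within/near (< 1 Mb) chromosomal inversions.
2. **Which SNPs diverge, and which look selected?** Per-locus allele
   frequencies, observed heterozygosity, genotype × taxon chi-square
   association with Bonferroni correction and noncentral-χ² power, plus an
   FDIST-style outlier scan that ranks each locus's (heterozygosity, θ)
   against a hierarchical-island structured-coalescent null (demes
   exchanging more migrants within than between groups; simulated in C++).
3. **How linked are the functional SNPs?** EM maximum-likelihood two-locus
   haplotype frequencies from unphased genotypes,
   r² = D²/(p_A(1−p_A)p_B(1−p_B)), summarized as proportions of
   within-gene and between-gene pairs exceeding r² thresholds
   0.5 / 0.8 / 0.95.

SNPs are classed as *potentially functional* when non-synonymous or
synonymous with a ≥ 2-fold codon-usage difference. A Balding–Nichols
synthetic-data generator (`gen_study_mimic()`) reproduces the study's
design scale — 12,519 genes with a 231-gene immune subset, immune SNPs at
F = 0.13 vs background 0.035, three taxa of 12/11/13 (or 167/87/194)
diploids, 2R inversions — so the full pipeline runs and is validated
without any external data.

## Worked example

```r
library(divscan)

cfg <- study_mimic_config(n_genes = 2000, immune_count = 100)
bundle <- gen_study_mimic(cfg, seed = 7)
bundle$genotypes
#> genotype_matrix: 36 individuals x 2000 loci
#> taxa: bamako (n=12), coluzzii (n=13), savanna (n=11)
#> missing calls: 0.00%

geneset_fst_test(bundle$genotypes, c("coluzzii", "bamako"),
                 bundle$genes, bundle$immune_ids, B = 1000, seed = 1)
#> resampling test (sampled, B = 1000): observed = 0.1659,
#>   null = 0.03325 +/- 0.0103 (SEM 0.0003258), p = 0.000999
```

The immune set's multilocus F_ST (0.166 over these 100 genes) sits far
above every one of the 1000 random non-immune gene sets (null mean 0.033),
so the add-one empirical p-value is at its floor 1/1001 ≈ 0.001: immune
genes are significantly more diverged between *A. coluzzii* and Bamako
than the genome background, exactly the behaviour the generator encodes
(immune F = 0.13 vs background 0.035).

The numbered scripts under `analysis/` run the whole study-shaped workflow
(simulate → per-locus statistics → LD → gene-set and inversion tests →
outlier scan), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_popstats.R   # mean H_obs, association counts, power
Rscript analysis/03_ld.R         # within/between-gene r2 threshold table
Rscript analysis/04_geneset_tests.R
Rscript analysis/05_outlier_scan.R
```

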