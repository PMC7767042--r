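---
title: "Measuring immune gene-set divergence among sympatric mosquito taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring immune gene-set divergence among sympatric mosquito taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The *Anopheles gambiae* species complex in West Africa contains three
closely related, sympatrically breeding taxa — *A. coluzzii* and the Bamako
and Savanna chromosomal forms of *A. gambiae* s.s. Because innate-immunity
genes mediate both survival of microbial challenges in larval habitats and
susceptibility to *Plasmodium*, divergence of immune signaling genes among
these taxa bears directly on malaria transmission and on the ecology of
incipient speciation. `divscan` implements the statistical machinery needed
to ask, from genotype data alone:

1. Are immune genes more diverged among taxa than random sets of non-immune
   genes?
2. Which individual SNPs are significantly associated with taxon, and which
   look like selection outliers rather than drift?
3. How strongly are the functional SNPs within and between immune genes
   linked?

A synthetic-data generator reproduces the statistical structure of the
two-armed study design — whole-genome sequencing of a few dozen individuals
across ~12,500 genes, and dense genotyping of a few hundred individuals at
a panel of putatively functional SNPs — so that every stage runs, and can
be validated, without access to field data.

## Data model

Genotypes are held as a `genotype_matrix`: individuals × biallelic loci,
each call the alternate-allele dosage 0/1/2 or `NA` for a missing call,
with one taxon label per individual and a SNP table carrying coordinates
(1-based, VCF convention), alleles, gene assignment and functional class.
Gene and inversion annotations use BED's 0-based half-open intervals; the
single point of conversion between the two conventions is
`assign_snps_to_genes()`, which places a SNP at 1-based position *p* inside
interval `[start, end)` iff `start < p <= end`. A SNP inside overlapping
genes is credited to each of them in per-gene statistics.

## Functional SNP classification

A coding SNP is *potentially functional* when it changes the encoded amino
acid, or when it exchanges synonymous codons whose genome-wide usage
frequencies differ at least 2-fold (a proxy for altered translation
kinetics and folding). Decisions taken where the criterion is
underspecified:

- the 2-fold threshold is inclusive (a ratio of exactly 2 qualifies), and
  the ratio is taken in whichever direction exceeds 1, making the
  classification symmetric in ref/alt;
- stop-gain and stop-loss changes are treated as amino-acid changes;
- a single genome-wide codon-usage table is used rather than per-gene
  tables, which is the standard operational choice when only a global table
  is available.

The codon usage table is an input file; the bundled example table is a
synthetic fixture, not an estimate for any real genome.

## Per-locus statistics

For each locus and taxon the package reports the alternate-allele frequency
(dosage sum over twice the non-missing individuals) and observed
heterozygosity `H_obs` (heterozygote fraction among non-missing
individuals), with per-taxon means and standard deviations across loci.
Association between genotype and taxon uses Pearson's chi-square on the
taxa × genotype-class table without continuity correction, dropping empty
genotype columns; degenerate tables (df = 0) yield `NA` with a flag.
Multiple testing uses Bonferroni at `alpha = 0.05` over the number of SNPs
tested — the most conservative standard choice, since the study design does
not pin the adjustment method down; the family size `m` is exposed.
`chisq_power()` gives the noncentral chi-square power `P(X > crit)` with
noncentrality `n * w^2` for effect size `w` (Cohen's w).

## Weir–Cockerham F_ST

Divergence uses the Weir & Cockerham (1984) variance components: `a`
(among populations), `b` (among individuals within populations) and `c`
(within individuals), with `theta = a / (a + b + c)` per locus. Estimates
are reported as computed — negative values are not clamped, so that
multilocus summaries average properly. The multilocus estimator is the
ratio of sums `sum(a) / sum(a + b + c)` over loci (the "weighted" F_ST of
VCFtools), which is far less noisy than averaging per-locus ratios. Loci
monomorphic across the chosen taxa have `a + b + c = 0` and are excluded
from the sums; their count is reported. Missing data are handled per locus
by complete cases within each taxon.

## Linkage disequilibrium by EM

Two-locus haplotype frequencies are estimated from unphased genotypes by
maximum likelihood. Of the nine two-locus genotype classes only the double
heterozygote is phase-ambiguous; the E-step splits it between coupling and
repulsion in proportion to the current haplotype products, and every
iterate keeps haplotype margins equal to the sample allele frequencies.
`r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))` with `D = p_AB - p_A p_B`.

Numerical choices: convergence when the log-likelihood gain drops below
`1e-8`, at most 1000 iterations, and 5 starts — the first at linkage
equilibrium, the rest at random phase splits. The restarts matter: when
every individual is doubly heterozygous the likelihood has two symmetric
maxima (full coupling and full repulsion) and the equilibrium start sits
exactly on the saddle between them. Ties between symmetric maxima are
broken toward the higher-|D| solution (r² is identical by symmetry) and
flagged as multimodal. Pairs with fewer than 5 pairwise-complete
individuals, or with a monomorphic member, return `NaN` with a flag. The
EM ascent property is asserted at every iteration.

The within-/between-gene threshold summary reports, for each partition and
each threshold in {0.5, 0.8, 0.95}, the proportion of pairs whose r²
exceeds it **among pairs with defined r²**; undefined pairs are counted
separately. (Whether such summaries should pool undefined pairs into the
denominator is ambiguous; the defined-pairs denominator is used and the
undefined count reported so either convention can be reconstructed.)

## Gene-set resampling tests

Genes — not SNPs — are the resampling unit, preserving within-gene LD under
the null. Three tests share one engine:

- **Gene-set F_ST**: ratio-of-sums theta of all SNPs in the immune set
  versus random equal-sized sets drawn without replacement from the
  non-immune pool, independently across replicates.
- **SNP count**: the number of SNP-gene assignments in the set, same
  scheme (null sets drawn from the full gene pool by default).
- **Inversion overlap**: a gene "hits" when its interval overlaps an
  inversion or lies within 1 Mb of one; observed immune hits versus random
  sets from all genes. A chromosome filter (e.g. 2R-only) is available,
  genome-wide being the default.

Empirical p-values use the add-one convention `(1 + #{null >= obs})/(B+1)`
and can never be zero; with `B = 1000` the floor is `1/1001 < 0.001`.
Exhaustive enumeration over all subsets replaces sampling on small pools,
reporting the exact upper-tail fraction. Genes inside configured exclusion
regions (the pericentromeric "speciation islands", where elevated
divergence is expected a priori) are removed from both the immune set and
the sampling pool before anything is computed.

## The hierarchical-island outlier scan

Selection outliers are flagged FDIST-style: each locus's (heterozygosity,
theta) pair is compared to the joint neutral distribution simulated under a
hierarchical island model, in which demes exchange more migrants within
than between groups (`M_w > M_b`). This inflates neutral F_ST variance
relative to a flat island model in the right way and so suppresses false
positives when the sampled populations are themselves structured.

The structured coalescent is simulated per locus: within-deme pair
coalescence at rate 1 (time in units of 2N per deme), per-lineage migration
at total rate `(M_w + M_b)/2` with destination uniform among same-group
demes with probability `M_w/(M_w + M_b)` and uniform among other-group
demes otherwise. One mutation is placed on the genealogy proportionally to
branch length, so every simulated locus is polymorphic in the pooled
sample; genotypes are formed by random pairing of gene copies within demes,
and W&C theta plus mean within-deme expected heterozygosity are recorded.
The dominant cost is the final coalescence of two lineages wandering among
~1000 demes; that phase is simulated as the lumped three-state jump chain
(same deme / same group / different groups), which is distributionally
exact and orders of magnitude faster than tracking every migration. The
simulator is implemented in C++ and driven by R's RNG, so `set.seed()`
governs it.

Null points are binned by heterozygosity quantiles (20 bins by default;
bins holding fewer than 20 points are merged) and each observed locus is
ranked within its bin: `p = (1 + #{null theta >= obs})/(n_bin + 1)`,
one-sided toward high F_ST. Defaults — 10 groups × 100 demes, `M_w = 20`,
`M_b = 2`, three sampled demes in three distinct groups mirroring the three
taxa, 20,000 simulations — are all exposed in the config; 20,000
simulations support p-values down to ~5 × 10⁻⁵. Because allele counts at
realistic sample sizes are discrete, null theta values carry ties and the
binned p-values are conservative rather than exactly uniform; the
calibration suite checks that the 5% tail is close to nominal and never
anticonservative.

## The synthetic-data generator

`gen_balding_nichols()` draws, per locus, an ancestral frequency
(Uniform(0.05, 0.95) by default, avoiding near-fixed ancestral SNPs), then
per-taxon frequencies from Beta(p(1−F)/F, (1−p)(1−F)/F) and
Hardy–Weinberg genotypes. Its `F` *is* the Weir–Cockerham estimand, which
is what makes the parameter-recovery suite meaningful: multilocus theta on
generated data must recover the generating `F` within ±0.015 across
`F ∈ {0.02, 0.05, 0.10, 0.15}`. Study-mimic defaults: 12,519 genes with a
231-gene immune subset, immune SNPs at `F = 0.13` and background at
`F = 0.035` (the magnitudes reported for immune vs genome-background
divergence in this system), whole-genome-scale samples of 12/11/13
diploids (with 167/87/194 available as the genotyping-scale preset), one
SNP per gene by default, and five chromosome-2R paracentric inversions.
Loci that land monomorphic are retained so downstream `NaN` paths stay
exercised.

What the generator deliberately does **not** emulate: demographic history
(bottlenecks, admixture, clines), selective sweeps, missing data,
genotyping error, real gene-length and SNP-density variation, and the
empirical site-frequency spectrum — the Uniform(0.05, 0.95) ancestral law
yields mean heterozygosity near 0.3, higher than the ~0.14 seen on the real
panel. Passing tests therefore demonstrate estimator correctness and
calibration under the stated model, not robustness to everything field data
can do.

`gen_ld_block()` builds unphased genotype blocks whose adjacent locus pairs
attain a target r² exactly in expectation (haplotype frequencies solved at
the given allele frequencies; infeasible targets error with the feasible
maximum), and the annotation generator places non-overlapping genes
uniformly per chromosome with an optional bias of immune genes toward
inversions.

## Pipeline and reproducibility

`run_full_analysis()` wires the stages — load/generate, functional filter,
per-locus statistics, pairwise F_ST, LD summaries, gene-set tests,
inversion permutation, outlier scan — writing one TSV per stage plus a
summary JSON, with every stage seeded from a single master seed through
fixed substream derivation, so reruns are byte-identical. The numbered
scripts under `analysis/` run the same stages as a narrative workflow over
a simulated study (stage outputs under `results/`); each stage re-reads its
inputs from disk, so any stage can be rerun alone.

Problem sizes used by the test suite are chosen to make the statistical
checks sharp while keeping a full run in minutes on one CPU: 2,000 loci ×
150 diploids for parameter recovery, 50 random small datasets for the EM
oracle comparison, 20,000 null simulations against 2,000 scanned loci for
outlier calibration, and 50 seeded pipeline runs for the null calibration
of the gene-set test.

## Known limitations

- The EM estimator targets two-locus haplotypes only; no multi-locus
  phasing, and D' is reported but not summarized.
- The outlier scan's null must be configured to resemble the sampling
  design; it is validated by self-calibration, not by matching any
  particular field dataset, and the discreteness of allele counts makes it
  conservative at small sample sizes.
- The SNP-count gene-set test inherits whatever SNP-density structure the
  input has; under the default generator all genes are exchangeable, so it
  is only informative on data with real density variation.
- Exact tests of Hardy–Weinberg equilibrium, haplotype-based F_ST and
  jackknife confidence intervals are out of scope.
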