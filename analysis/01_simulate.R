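#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Two bundles are written, mirroring the two arms of the study design:
#   - a whole-genome-scale bundle: 12,519 genes (231 immune) at one SNP per
#     gene, 12/11/13 diploids, immune SNPs at Balding-Nichols F = 0.13 and
#     background at 0.035;
#   - a genotyping-scale panel: 58 "immune signaling" genes carrying a few
#     SNPs each in within-gene LD, sampled for 167/87/194 individuals.
# All downstream stages read these files from results/data/.

suppressPackageStartupMessages(library(divscan))

seed <- 20201101L
wgs_dir <- "results/data/wgs"
panel_dir <- "results/data/panel"

message("Writing whole-genome-scale bundle to ", wgs_dir)
# variable SNP counts per gene and immune placement biased toward the 2R
# inversions, emulating the observed clustering of immune genes there
wgs_cfg <- study_mimic_config(
  snps_per_gene = function(n) 1L + rpois(n, 1),
  immune_placement_bias = 0.5)
wgs <- gen_study_mimic(wgs_cfg, seed = seed, out_dir = wgs_dir)
message(sprintf("  %d individuals x %d SNPs in %d genes (%d immune)",
                nrow(wgs$genotypes$calls), ncol(wgs$genotypes$calls),
                nrow(wgs$genes), length(wgs$immune_ids)))

message("Writing genotyping-scale panel to ", panel_dir)
panel_cfg <- study_mimic_config(
  scale = "genotyping", n_genes = 58L, immune_count = 58L,
  snps_per_gene = function(n) 3L + rpois(n, 2.7),  # ~333 SNPs over 58 genes
  ld_block_r2 = 0.9)
panel <- gen_study_mimic(panel_cfg, seed = seed + 1L, out_dir = panel_dir)
message(sprintf("  %d individuals x %d SNPs in %d genes",
                nrow(panel$genotypes$calls), ncol(panel$genotypes$calls),
                nrow(panel$genes)))
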