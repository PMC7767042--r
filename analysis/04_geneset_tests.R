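#!/usr/bin/env Rscript
# Stage 4: gene-set divergence tests on the whole-genome-scale bundle.
#
# For each pairwise taxon contrast: the multilocus (ratio-of-sums)
# Weir-Cockerham F_ST of the 231-gene immune set versus 1000 random
# equal-sized non-immune gene sets (add-one empirical p). Also the
# SNP-count bootstrap and the inversion-overlap permutation test.
# Writes results/genesets/.

suppressPackageStartupMessages(library(divscan))

wgs_dir <- "results/data/wgs"
gm <- read_vcf(file.path(wgs_dir, "genotypes.vcf"),
               file.path(wgs_dir, "taxa.tsv"))
ann <- read_annotations(file.path(wgs_dir, "genes.bed"),
                        file.path(wgs_dir, "inversions.bed"),
                        file.path(wgs_dir, "immune_genes.txt"))
gm <- assign_snps_to_genes(gm, ann$genes)
immune <- ann$genes$gene_id[ann$genes$immune]

contrasts <- combn(taxa(gm), 2, simplify = FALSE)
rows <- list()
nulls <- list()
for (ct in contrasts) {
  key <- paste(ct, collapse = "_vs_")
  res <- geneset_fst_test(gm, ct, ann$genes, immune, B = 1000L,
                          seed = 40L + length(rows))
  message(sprintf(
    "%-22s immune set F_ST = %.3f vs null %.3f +/- %.3f -> p = %.4g",
    key, res$observed, res$null_mean, res$null_sd, res$p_value))
  rows[[key]] <- data.frame(test = "geneset_fst", contrast = key,
                            observed = res$observed,
                            null_mean = res$null_mean,
                            null_sd = res$null_sd, null_sem = res$null_sem,
                            p_value = res$p_value, B = res$B)
  nulls[[key]] <- data.frame(contrast = key, null_fst = res$null)
}

snp_res <- geneset_snpcount_test(gm, ann$genes, immune, B = 1000L, seed = 77L)
message(sprintf(
  "immune SNP count = %d vs null %.1f +/- %.1f (SEM %.2f) -> p = %.4g",
  snp_res$observed, snp_res$null_mean, snp_res$null_sd, snp_res$null_sem,
  snp_res$p_value))
rows$snpcount <- data.frame(test = "geneset_snpcount", contrast = "all",
                            observed = snp_res$observed,
                            null_mean = snp_res$null_mean,
                            null_sd = snp_res$null_sd,
                            null_sem = snp_res$null_sem,
                            p_value = snp_res$p_value, B = snp_res$B)

inv_res <- inversion_overlap_test(ann$genes, immune, ann$inversions,
                                  near_distance = 1e6, B = 1000L, seed = 78L)
message(sprintf(
  "immune genes within/near inversions = %d vs null %.1f +/- %.2f -> p = %.4g",
  inv_res$observed, inv_res$null_mean, inv_res$null_sd, inv_res$p_value))
rows$inversion <- data.frame(test = "inversion_overlap", contrast = "all",
                             observed = inv_res$observed,
                             null_mean = inv_res$null_mean,
                             null_sd = inv_res$null_sd,
                             null_sem = inv_res$null_sem,
                             p_value = inv_res$p_value, B = inv_res$B)

write_results(list(geneset_tests = do.call(rbind, rows),
                   fst_null_distributions = do.call(rbind, nulls)),
              "results/genesets")
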