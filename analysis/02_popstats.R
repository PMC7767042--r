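#!/usr/bin/env Rscript
# Stage 2: per-locus population statistics on the genotyping-scale panel.
#
# Computes per-taxon allele frequencies and observed heterozygosity,
# genotype-taxon chi-square association with Bonferroni adjustment over the
# panel size, and a power curve for the association test at the realized
# sample size. Writes results/popstats/.

suppressPackageStartupMessages(library(divscan))

panel_dir <- "results/data/panel"
gm <- read_vcf(file.path(panel_dir, "genotypes.vcf"),
               file.path(panel_dir, "taxa.tsv"))
ann <- read_annotations(file.path(panel_dir, "genes.bed"),
                        file.path(panel_dir, "inversions.bed"),
                        file.path(panel_dir, "immune_genes.txt"))
gm <- assign_snps_to_genes(gm, ann$genes)

het <- lapply(setNames(nm = taxa(gm)), observed_heterozygosity, x = gm)
for (tx in taxa(gm))
  message(sprintf("%-9s mean H_obs = %.3f (sd %.3f), invariant SNPs = %d",
                  tx, het[[tx]]$mean, het[[tx]]$sd, het[[tx]]$n_invariant))

assoc <- association_scan(gm)
message(sprintf("%d of %d SNPs significantly associated with taxon (p < %.2g)",
                sum(assoc$significant, na.rm = TRUE), nrow(assoc),
                attr(assoc, "threshold")))
diverged_genes <- unique(gm$snps$gene_id[match(
  assoc$locus[assoc$significant], gm$snps$id)])
message(sprintf("diverged genes (>= 1 significant SNP): %d of %d",
                length(diverged_genes), nrow(ann$genes)))

per_locus <- data.frame(locus = gm$snps$id, chrom = gm$snps$chrom,
                        pos = gm$snps$pos, gene = gm$snps$gene_id)
for (tx in taxa(gm)) {
  per_locus[[paste0("freq_", tx)]] <-
    sapply(seq_len(ncol(gm$calls)), function(j)
      allele_frequency(gm, tx, j)$freq)
  per_locus[[paste0("hobs_", tx)]] <- het[[tx]]$per_locus
}
per_locus <- cbind(per_locus,
                   assoc[, c("chi2", "df", "p_value", "significant")])

# power of the genotype association chi-square at the panel sample size
n_total <- nrow(gm$calls)
power_tab <- do.call(rbind, lapply(c(0.1, 0.2, 0.3, 0.5), function(w)
  data.frame(effect_w = w, df = 4, n = n_total,
             power = chisq_power(w, 4, n_total,
                                 alpha = attr(assoc, "threshold")))))
message("power at Bonferroni alpha, df = 4: ",
        paste(sprintf("w=%.1f: %.3f", power_tab$effect_w, power_tab$power),
              collapse = ", "))

write_results(list(per_locus = per_locus, power = power_tab,
                   heterozygosity = data.frame(
                     taxon = taxa(gm),
                     mean_hobs = sapply(het, `[[`, "mean"),
                     sd_hobs = sapply(het, `[[`, "sd"),
                     n_invariant = sapply(het, `[[`, "n_invariant"))),
              "results/popstats")
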