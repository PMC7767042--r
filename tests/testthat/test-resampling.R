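# Gene-set bootstrap and inversion permutation tests, checked against
# exhaustive enumeration on toy problems and calibration properties.

# toy annotation: k genes laid side by side on one chromosome
toy_genes <- function(n, chrom = "2R", len = 100L) {
  data.frame(gene_id = paste0("g", seq_len(n)), chrom = chrom,
             start = (seq_len(n) - 1L) * len, end = seq_len(n) * len,
             stringsAsFactors = FALSE)
}

# genotype matrix with one SNP per gene and per-gene divergence chosen so
# per-locus theta is high for `hot` genes
toy_gene_snps <- function(genes, hot, n_per_taxon = 30, seed = 1) {
  set.seed(seed)
  Fv <- ifelse(genes$gene_id %in% hot, 0.6, 0.02)
  snps <- data.frame(id = paste0(genes$gene_id, "_s1"), chrom = genes$chrom,
                     pos = genes$start + 50L, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  gm <- gen_balding_nichols(c(tx1 = n_per_taxon, tx2 = n_per_taxon),
                            nrow(genes), Fv, snps = snps)
  assign_snps_to_genes(gm, genes)
}

test_that("gene-set F_ST p matches exhaustive subset enumeration", {
  genes <- toy_genes(5)
  gm <- toy_gene_snps(genes, hot = c("g1", "g2"), seed = 42)
  res <- geneset_fst_test(gm, c("tx1", "tx2"), genes,
                          immune_gene_ids = c("g1", "g2"),
                          pool = "all", exhaustive = TRUE)
  # enumeration oracle over per-locus components
  comp <- wc_fst_all_loci(gm, c("tx1", "tx2"))
  tot <- comp$a + comp$b + comp$c
  set_fst <- function(idx) sum(comp$a[idx]) / sum(tot[idx])
  obs <- set_fst(1:2)
  subsets <- combn(5, 2, simplify = FALSE)
  exact_p <- mean(sapply(subsets, set_fst) >= obs)
  expect_equal(res$B, 10L)
  expect_equal(res$p_value, exact_p)
  expect_equal(res$observed, obs)
})

test_that("sampled p converges to the exhaustive p", {
  genes <- toy_genes(8)
  gm <- toy_gene_snps(genes, hot = c("g1", "g2", "g3"), seed = 8)
  exact <- geneset_fst_test(gm, c("tx1", "tx2"), genes,
                            immune_gene_ids = c("g1", "g2", "g3"),
                            pool = "all", exhaustive = TRUE)
  B <- 2000L
  sampled <- geneset_fst_test(gm, c("tx1", "tx2"), genes,
                              immune_gene_ids = c("g1", "g2", "g3"),
                              pool = "all", B = B, seed = 99)
  p <- exact$p_value
  expect_lt(abs(sampled$p_value - p), 2 * sqrt(p * (1 - p) / B) + 2 / B)
})

test_that("SNP-count test enumerates exactly and is degenerate-safe", {
  genes <- toy_genes(4)
  # genes carry 10, 1, 1, 1 SNPs
  assignments <- data.frame(
    snp_id = paste0("s", 1:13),
    gene_id = rep(c("g1", "g2", "g3", "g4"), c(10, 1, 1, 1)),
    stringsAsFactors = FALSE)
  res <- geneset_snpcount_test(assignments, genes,
                               immune_gene_ids = "g1", pool = "all",
                               exhaustive = TRUE)
  expect_equal(res$p_value, 1 / 4)
  expect_equal(res$observed, 10)
  # all genes equal -> every null value equals the observed; p = 1
  eq <- data.frame(snp_id = paste0("e", 1:8),
                   gene_id = rep(paste0("g", 1:4), each = 2))
  res_eq <- geneset_snpcount_test(eq, genes, immune_gene_ids = c("g1", "g2"),
                                  B = 50, seed = 2)
  expect_equal(res_eq$p_value, 1)
  expect_equal(res_eq$null_sd, 0)
})

test_that("null mean of the SNP-count test matches the sampling expectation", {
  set.seed(60)
  genes <- toy_genes(40)
  counts <- rpois(40, 5) + 1L
  assignments <- data.frame(
    snp_id = paste0("s", seq_len(sum(counts))),
    gene_id = rep(genes$gene_id, counts), stringsAsFactors = FALSE)
  immune <- paste0("g", 1:8)
  res <- geneset_snpcount_test(assignments, genes, immune_gene_ids = immune,
                               B = 1000, seed = 3, pool = "non_focal")
  pool_mean <- mean(counts[9:40])
  expect_lt(abs(res$null_mean - 8 * pool_mean), 3 * 8 * sd(counts[9:40]))
})

test_that("inversion overlap test enumerates the toy case exactly", {
  genes <- toy_genes(4, len = 1000L)            # genes span 0..4000
  inversions <- data.frame(name = "inv1", chrom = "2R",
                           start = 0L, end = 1995L)
  # with near_distance 0-ish only g1, g2 overlap
  res <- inversion_overlap_test(genes, immune_gene_ids = c("g1", "g2"),
                                inversions, near_distance = 0,
                                pool = "all", exhaustive = TRUE)
  expect_equal(res$observed, 2)
  expect_equal(res$null_mean, 1)
  expect_equal(res$p_value, 1 / 6)
  # inversion covering everything: every subset saturates, p = 1
  inv_all <- data.frame(name = "inv", chrom = "2R", start = 0L, end = 5000L)
  res_all <- inversion_overlap_test(genes, immune_gene_ids = c("g1", "g2"),
                                    inv_all, pool = "all", exhaustive = TRUE)
  expect_equal(res_all$p_value, 1)
  expect_error(inversion_overlap_test(genes, immune_gene_ids = "g1",
                                      inversions = NULL), "no inversions")
})

test_that("near-distance hits include genes within but not beyond the window", {
  genes <- data.frame(gene_id = c("inside", "near", "far"), chrom = "2R",
                      start = c(5000L, 12000L, 2000000L),
                      end = c(6000L, 13000L, 2001000L))
  inversions <- data.frame(name = "inv", chrom = "2R", start = 4000L,
                           end = 8000L)
  hit <- gene_inversion_hits(genes, inversions, near_distance = 10000)
  expect_equal(hit, c(TRUE, TRUE, FALSE))
})

test_that("random focal sets give calibrated, never-zero p-values", {
  set.seed(70)
  genes <- toy_genes(60)
  gm <- toy_gene_snps(genes, hot = character(0), seed = 11)
  ps <- replicate(200, {
    focal <- sample(genes$gene_id, 10)
    geneset_fst_test(gm, c("tx1", "tx2"), genes, immune_gene_ids = focal,
                     B = 99)$p_value
  })
  expect_true(all(ps > 0))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("seeds control the null sample reproducibly", {
  genes <- toy_genes(30)
  gm <- toy_gene_snps(genes, hot = "g1", seed = 21)
  imm <- paste0("g", 1:5)
  r1 <- geneset_fst_test(gm, c("tx1", "tx2"), genes, imm, B = 200, seed = 5)
  r2 <- geneset_fst_test(gm, c("tx1", "tx2"), genes, imm, B = 200, seed = 5)
  expect_identical(r1$null, r2$null)
  r3 <- geneset_fst_test(gm, c("tx1", "tx2"), genes, imm, B = 200, seed = 6)
  expect_false(identical(r1$null, r3$null))
  sem <- sqrt(r1$null_sem^2 + r3$null_sem^2)
  expect_lt(abs(r1$null_mean - r3$null_mean), 4 * sem)
})

test_that("exclusion regions drop genes from both the set and the pool", {
  genes <- toy_genes(10)
  gm <- toy_gene_snps(genes, hot = "g1", seed = 31)
  excl <- data.frame(name = "island", chrom = "2R", start = 0L, end = 150L)
  res <- geneset_fst_test(gm, c("tx1", "tx2"), genes,
                          immune_gene_ids = c("g1", "g2", "g3"),
                          B = 50, seed = 1, exclude_bed = excl)
  # g1 (0-100) and g2 (100-200) overlap the exclusion; only g3 remains focal
  comp <- wc_fst_all_loci(gm, c("tx1", "tx2"))
  tot <- comp$a + comp$b + comp$c
  expect_equal(res$observed, comp$a[3] / tot[3])
})
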