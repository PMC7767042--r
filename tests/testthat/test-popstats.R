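# Allele frequencies, heterozygosity, chi-square association, power, and
# the Weir-Cockerham F_ST estimator.

test_that("allele frequencies count alt alleles over non-missing calls", {
  gm <- gm_from_counts(table2_counts[["MAP2K4-164"]]["coluzzii"])
  af <- allele_frequency(gm, "coluzzii", 1)
  expect_equal(af$freq, 1 / 330)
  expect_equal(af$allele_count, 330L)
  gm2 <- gm_from_counts(list(t = c(0, 0, 4)))
  expect_equal(allele_frequency(gm2, "t", 1)$freq, 1)
  gm3 <- gm_from_counts(list(t = c(1, 1, 1)))
  expect_equal(allele_frequency(gm3, "t", 1)$freq, 0.5)
  gm4 <- genotype_matrix(matrix(NA_integer_, 2, 1), c("t", "t"),
                         data.frame(id = "s", chrom = "1", pos = 1,
                                    ref = "A", alt = "T"))
  expect_warning(af4 <- allele_frequency(gm4, "t", 1), "all calls missing")
  expect_true(is.nan(af4$freq))
})

test_that("observed heterozygosity is the heterozygote fraction", {
  gm <- gm_from_counts(table2_counts[["MAP2K4-164"]]["coluzzii"])
  h <- observed_heterozygosity(gm, "coluzzii")
  expect_equal(unname(h$per_locus), 1 / 165)
  expect_equal(unname(observed_heterozygosity(
    gm_from_counts(list(t = c(0, 6, 0))), "t")$per_locus), 1)
  mono <- observed_heterozygosity(gm_from_counts(list(t = c(6, 0, 0))), "t")
  expect_equal(unname(mono$per_locus), 0)
  expect_equal(mono$n_invariant, 1L)
})

test_that("chi-square association matches hand arithmetic and the oracle", {
  # 2x2 diagonal table: expected 5 per cell, chi2 = 20
  gm <- gm_from_counts(list(t1 = c(10, 0, 0), t2 = c(0, 0, 10)))
  res <- genotype_association(gm, 1)
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1L)
  # identical distributions -> chi2 0, p 1
  gm2 <- gm_from_counts(list(t1 = c(4, 3, 3), t2 = c(4, 3, 3)))
  res2 <- genotype_association(gm2, 1)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p_value, 1)
  # printed three-taxon genotype tables agree with the textbook formula
  for (snp in names(table2_counts)) {
    gm3 <- gm_from_counts(table2_counts[[snp]], snp)
    res3 <- genotype_association(gm3, 1)
    tab <- do.call(rbind, table2_counts[[snp]])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    want <- chisq_oracle(tab)
    expect_equal(res3$chi2, want$chi2, tolerance = 1e-9)
    expect_equal(res3$df, want$df)
    expect_equal(res3$p_value, want$p, tolerance = 1e-9)
  }
  # monomorphic locus is degenerate
  gm4 <- gm_from_counts(list(t1 = c(5, 0, 0), t2 = c(5, 0, 0)))
  res4 <- genotype_association(gm4, 1)
  expect_true(res4$degenerate)
  expect_true(is.na(res4$p_value))
})

test_that("Bonferroni flags use p < alpha/m", {
  adj <- bonferroni_adjust(c(1e-6, 0.01, NA), m = 333)
  expect_equal(adj$threshold, 0.05 / 333)
  expect_equal(adj$significant, c(TRUE, FALSE, FALSE))
  expect_true(bonferroni_adjust(0.04, m = 1)$significant)
  expect_false(bonferroni_adjust(0.06, m = 1)$significant)
})

test_that("chi-square power matches a data-level Monte-Carlo experiment", {
  expect_equal(chisq_power(0, 2, 400), 0.05)
  # monotone in n
  pw <- sapply(c(50, 100, 200, 400), function(n) chisq_power(0.3, 2, n))
  expect_true(all(diff(pw) > 0))
  expect_gte(chisq_power(0.5, 2, 400), 0.999)
  # independent check: goodness-of-fit data simulated at a known Cohen's w
  p0 <- rep(1 / 3, 3)
  delta <- c(2, -1, -1)
  scale <- sqrt(0.09 / sum(delta^2 / p0))  # w = 0.3
  p1 <- p0 + delta * scale
  w <- sqrt(sum((p1 - p0)^2 / p0))
  set.seed(31)
  n <- 150
  rej <- replicate(3000, {
    x <- rmultinom(1, n, p1)[, 1]
    stat <- sum((x - n * p0)^2 / (n * p0))
    stat > qchisq(0.95, 2)
  })
  expect_equal(mean(rej), chisq_power(w, 2, n), tolerance = 0.025)
})

test_that("association p-values are uniform under the null", {
  set.seed(12)
  gm <- gen_balding_nichols(c(a = 100, b = 100), 2000, 1e-9,
                            ancestral_freq_sampler = function(n)
                              runif(n, 0.2, 0.8))
  scan <- association_scan(gm)
  p <- scan$p_value[!is.na(scan$p_value)]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("W&C theta hits the fixed-difference and no-divergence limits", {
  fixed <- gm_from_counts(list(p1 = c(10, 0, 0), p2 = c(0, 0, 10)))
  expect_equal(wc_fst_locus(fixed, c("p1", "p2"), 1)$theta, 1)
  same <- gm_from_counts(list(p1 = c(4, 4, 2), p2 = c(4, 4, 2)))
  expect_lte(wc_fst_locus(same, c("p1", "p2"), 1)$theta, 0)
  mono <- gm_from_counts(list(p1 = c(8, 0, 0), p2 = c(9, 0, 0)))
  expect_true(is.nan(wc_fst_locus(mono, c("p1", "p2"), 1)$theta))
})

test_that("W&C components match the printed three-taxon genotype counts", {
  for (snp in names(table2_counts)) {
    gm <- gm_from_counts(table2_counts[[snp]], snp)
    got <- wc_fst_locus(gm, names(table2_counts[[snp]]), 1)
    want <- wc_oracle_counts(table2_counts[[snp]])
    expect_equal(got$a, want$a, tolerance = 1e-9)
    expect_equal(got$b, want$b, tolerance = 1e-9)
    expect_equal(got$c, want$c, tolerance = 1e-9)
    expect_equal(got$theta, want$theta, tolerance = 1e-9)
  }
})

test_that("W&C estimator equals the scalar transcription on random data", {
  set.seed(77)
  for (rep in 1:100) {
    n_pops <- sample(2:3, 1)
    counts <- lapply(seq_len(n_pops), function(i) {
      repeat {
        x <- rmultinom(1, sample(5:20, 1), runif(3, 0.1, 1))[, 1]
        if (sum(x) >= 2) return(x)
      }
    })
    names(counts) <- paste0("p", seq_len(n_pops))
    poly <- any(sapply(counts, function(x) x[2] + 2 * x[3]) > 0) &&
      any(sapply(counts, function(x) x[2] + 2 * x[1]) > 0)
    if (!poly) next
    gm <- gm_from_counts(counts)
    got <- wc_fst_locus(gm, names(counts), 1)
    want <- wc_oracle_counts(counts)
    expect_equal(got$theta, want$theta, tolerance = 1e-9)
  }
})

test_that("multilocus theta is a ratio of sums with the stated invariances", {
  set.seed(5)
  gm <- gen_balding_nichols(c(a = 20, b = 20), 10, 0.2)
  one <- wc_fst_locus(gm, c("a", "b"), 3)
  expect_equal(as.numeric(wc_fst_set(gm, c("a", "b"), loci = 3)), one$theta)
  # duplicating every locus leaves theta_set unchanged
  dup <- subset_genotypes(gm, loci = rep(1:10, 2))
  expect_equal(as.numeric(wc_fst_set(dup, c("a", "b"))),
               as.numeric(wc_fst_set(gm, c("a", "b"))))
})

test_that("pooling identical populations gives theta near zero", {
  set.seed(6)
  gm <- gen_balding_nichols(c(a = 50, b = 50), 1000, 1e-9)
  theta <- wc_fst_set(gm, c("a", "b"))
  expect_lt(abs(as.numeric(theta)), 0.01)
})

test_that("missing calls are handled per-locus complete-case", {
  calls <- rbind(c(0L, NA), c(1L, 0L), c(2L, NA), c(NA, 2L),
                 c(0L, 2L), c(1L, 2L))
  gm <- genotype_matrix(calls, rep(c("x", "y"), each = 3),
                        data.frame(id = c("s1", "s2"), chrom = "1",
                                   pos = 1:2, ref = "A", alt = "T"))
  af <- allele_frequency(gm, "x", 2)
  expect_equal(af$freq, 0)       # only one non-missing call (dosage 0)
  expect_equal(af$allele_count, 2L)
  got <- wc_fst_locus(gm, c("x", "y"), 1)
  want <- wc_oracle(n = c(3, 2), p = c(3 / 6, 1 / 4), h = c(1 / 3, 1 / 2))
  expect_equal(got$theta, want$theta, tolerance = 1e-12)
})
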