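# Per-locus population statistics: allele frequencies, observed
# heterozygosity, genotype-taxon chi-square association, chi-square power,
# and Weir & Cockerham (1984) F_ST variance components. The W&C estimator
# is the quantity every downstream test (gene-set bootstrap, outlier scan)
# is built on, so the component formulas live in one vectorized function.

#' Alternate-allele frequency in one taxon at one locus
#'
#' @param x a `genotype_matrix`.
#' @param taxon taxon label.
#' @param locus locus id (character) or column index.
#' @return list with `freq` (alt-allele frequency among non-missing calls),
#'   `alt_count` (alt alleles observed) and `allele_count` (2 x non-missing
#'   individuals). `freq` is `NaN` with a warning when all calls are
#'   missing.
#' @export
allele_frequency <- function(x, taxon, locus) {
  g <- taxon_calls(x, taxon, locus)[, 1L]
  n <- sum(!is.na(g))
  if (n == 0L) {
    warning("all calls missing for taxon '", taxon, "' at locus; freq is NaN")
    return(list(freq = NaN, alt_count = 0L, allele_count = 0L))
  }
  alt <- sum(g, na.rm = TRUE)
  list(freq = alt / (2 * n), alt_count = as.integer(alt),
       allele_count = 2L * n)
}

#' Observed heterozygosity per locus and its summary
#'
#' H_obs at a locus is the fraction of non-missing individuals that are
#' heterozygous (dosage 1). The mean and standard deviation are taken over
#' loci with at least one call in the taxon.
#'
#' @param x a `genotype_matrix`.
#' @param taxon taxon label.
#' @return list with `per_locus` (named numeric, NaN where no calls),
#'   `mean`, `sd`, and `n_invariant` (loci with calls but no variation in
#'   this taxon).
#' @export
observed_heterozygosity <- function(x, taxon) {
  g <- taxon_calls(x, taxon)
  n_called <- colSums(!is.na(g))
  n_het <- colSums(g == 1L, na.rm = TRUE)
  h <- ifelse(n_called > 0L, n_het / n_called, NaN)
  names(h) <- x$snps$id
  called <- n_called > 0L
  mono <- called & (colSums(g == 0L, na.rm = TRUE) == n_called |
                    colSums(g == 2L, na.rm = TRUE) == n_called)
  list(per_locus = h, mean = mean(h[called]), sd = sd(h[called]),
       n_invariant = sum(mono))
}

#' Chi-square association between genotype and taxon at one locus
#'
#' Builds the taxa x genotype-class (0/1/2) contingency table over
#' non-missing calls, drops empty genotype columns and taxa with no calls,
#' and applies Pearson's chi-square without continuity correction. When the
#' table is degenerate (fewer than 2 taxa or 2 genotype classes, df = 0)
#' the p-value is `NA` and `degenerate` is set.
#'
#' @param x a `genotype_matrix`.
#' @param locus locus id or column index.
#' @param allelic if `TRUE`, test the 2-class allele-count table instead of
#'   the 3-class genotype table.
#' @return list: `locus`, `chi2`, `df`, `p_value`, `table`, `degenerate`.
#' @export
genotype_association <- function(x, locus, allelic = FALSE) {
  jj <- if (is.character(locus)) match(locus, x$snps$id) else locus
  g <- x$calls[, jj]
  keep <- !is.na(g)
  if (allelic) {
    tab <- rbind(ref = tapply(2L - g[keep], x$taxon[keep], sum),
                 alt = tapply(g[keep], x$taxon[keep], sum))
    tab <- t(tab)
  } else {
    tab <- table(taxon = x$taxon[keep], genotype = factor(g[keep],
                                                          levels = 0:2))
    tab <- unclass(tab)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(locus = x$snps$id[jj], chi2 = NA_real_, df = 0L,
                p_value = NA_real_, table = tab, degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(locus = x$snps$id[jj], chi2 = unname(ct$statistic),
       df = as.integer(unname(ct$parameter)), p_value = ct$p.value,
       table = tab, degenerate = FALSE)
}

#' Chi-square association across all loci
#'
#' @inheritParams genotype_association
#' @param alpha,m Bonferroni family-wise level and number of tests; `m`
#'   defaults to the number of loci tested.
#' @return data.frame: locus, chi2, df, p_value, significant (Bonferroni).
#' @export
association_scan <- function(x, allelic = FALSE, alpha = 0.05, m = NULL) {
  res <- lapply(seq_len(ncol(x$calls)), function(j)
    genotype_association(x, j, allelic = allelic))
  out <- data.frame(locus = vapply(res, `[[`, "", "locus"),
                    chi2 = vapply(res, `[[`, 0, "chi2"),
                    df = vapply(res, function(r) as.numeric(r$df), 0),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  if (is.null(m)) m <- sum(!is.na(out$p_value))
  adj <- bonferroni_adjust(out$p_value, m = m, alpha = alpha)
  out$significant <- adj$significant
  attr(out, "threshold") <- adj$threshold
  out
}

#' Bonferroni adjustment flags
#'
#' A test is flagged significant iff p < alpha / m.
#'
#' @param p_values numeric vector (NA allowed; never significant).
#' @param m number of comparisons (>= number of tests); defaults to
#'   `length(p_values)`.
#' @param alpha family-wise error rate.
#' @return list: `significant` (logical vector), `threshold` (alpha/m).
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1)
  thr <- alpha / m
  list(significant = !is.na(p_values) & p_values < thr, threshold = thr)
}

#' Power of the chi-square test
#'
#' Power at effect size `w` (Cohen's w) and total sample size `n`:
#' P(X > chi2_crit) for X noncentral chi-square with df `df` and
#' noncentrality n * w^2.
#'
#' @param effect_size_w Cohen's w (>= 0).
#' @param df degrees of freedom.
#' @param n total count.
#' @param alpha test level.
#' @return power in [alpha, 1].
#' @export
chisq_power <- function(effect_size_w, df, n, alpha = 0.05) {
  stopifnot(effect_size_w >= 0, n >= 1)
  crit <- qchisq(1 - alpha, df)
  pchisq(crit, df, ncp = n * effect_size_w^2, lower.tail = FALSE)
}

# Weir & Cockerham (1984) two-allele variance components, vectorized over
# loci. Inputs are loci x population matrices: nmat = diploid sample sizes
# (non-missing), pmat = alt-allele frequencies, hmat = observed heterozygote
# proportions. Populations with nmat == 0 at a locus drop out of that
# locus's sums. Returns data.frame with a, b, c, r (pops used).
wc_components <- function(nmat, pmat, hmat) {
  nmat <- as.matrix(nmat); pmat <- as.matrix(pmat); hmat <- as.matrix(hmat)
  pmat[nmat == 0] <- 0; hmat[nmat == 0] <- 0
  r <- rowSums(nmat > 0)
  nsum <- rowSums(nmat)
  nbar <- nsum / r
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pbar <- rowSums(nmat * pmat) / nsum
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  data.frame(a = a, b = b, c = c_, r = r)
}

# Extract nmat/pmat/hmat for given taxa from a genotype_matrix.
wc_inputs <- function(x, taxa_subset) {
  mats <- lapply(taxa_subset, function(tx) taxon_calls(x, tx))
  nmat <- sapply(mats, function(g) colSums(!is.na(g)))
  altmat <- sapply(mats, function(g) colSums(g, na.rm = TRUE))
  hetmat <- sapply(mats, function(g) colSums(g == 1L, na.rm = TRUE))
  if (ncol(x$calls) == 1L) {
    nmat <- matrix(nmat, nrow = 1L); altmat <- matrix(altmat, nrow = 1L)
    hetmat <- matrix(hetmat, nrow = 1L)
  }
  pmat <- ifelse(nmat > 0, altmat / (2 * nmat), 0)
  hmat <- ifelse(nmat > 0, hetmat / nmat, 0)
  list(n = nmat, p = pmat, h = hmat)
}

#' Weir-Cockerham F_ST at a single locus
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components of Weir &
#' Cockerham (1984) and theta = a / (a + b + c). Negative estimates are
#' reported as computed, not clamped. A locus monomorphic across all taxa
#' has a + b + c = 0 and theta `NaN`.
#'
#' @param x a `genotype_matrix`.
#' @param taxa_subset taxa to contrast (>= 2 labels).
#' @param locus locus id or column index.
#' @return list: `locus`, `a`, `b`, `c`, `theta`, `n_pops`, `n` (per-taxon
#'   non-missing sample sizes).
#' @export
wc_fst_locus <- function(x, taxa_subset, locus) {
  jj <- if (is.character(locus)) match(locus, x$snps$id) else locus
  sub <- subset_genotypes(x, individuals = x$taxon %in% taxa_subset,
                          loci = jj)
  inp <- wc_inputs(sub, taxa_subset)
  comp <- wc_components(inp$n, inp$p, inp$h)
  tot <- comp$a + comp$b + comp$c
  theta <- ifelse(is.na(tot) | tot == 0, NaN, comp$a / tot)
  list(locus = x$snps$id[jj], a = comp$a, b = comp$b, c = comp$c,
       theta = theta, n_pops = comp$r,
       n = setNames(as.numeric(inp$n[1, ]), taxa_subset))
}

#' Weir-Cockerham components for every locus
#'
#' Vectorized version of [wc_fst_locus()] over all loci of the matrix.
#'
#' @inheritParams wc_fst_locus
#' @return data.frame: locus, a, b, c, theta (NaN where monomorphic or
#'   undefined).
#' @export
wc_fst_all_loci <- function(x, taxa_subset = taxa(x)) {
  inp <- wc_inputs(x, taxa_subset)
  comp <- wc_components(inp$n, inp$p, inp$h)
  tot <- comp$a + comp$b + comp$c
  data.frame(locus = x$snps$id, a = comp$a, b = comp$b, c = comp$c,
             theta = ifelse(is.na(tot) | tot == 0, NaN, comp$a / tot),
             stringsAsFactors = FALSE)
}

#' Multilocus (ratio-of-sums) Weir-Cockerham F_ST
#'
#' The weighted estimator theta_set = sum(a) / sum(a + b + c) over loci,
#' the convention VCFtools reports as "weighted Fst". Loci with undefined
#' components (monomorphic across the chosen taxa, or insufficient data)
#' are excluded from both sums; their count is available as attribute
#' `"n_excluded"`.
#'
#' @param x a `genotype_matrix`.
#' @param taxa_subset taxa to contrast.
#' @param loci optional locus selector (ids or indices); default all.
#' @return numeric theta_set (NaN when no usable locus), with attributes
#'   `n_loci` (used) and `n_excluded`.
#' @export
wc_fst_set <- function(x, taxa_subset = taxa(x), loci = NULL) {
  if (!is.null(loci)) x <- subset_genotypes(x, loci = loci)
  comp <- wc_fst_all_loci(x, taxa_subset)
  fst_from_components(comp)
}

# Ratio-of-sums theta from a per-locus component table (a, b, c columns).
fst_from_components <- function(comp) {
  tot <- comp$a + comp$b + comp$c
  usable <- is.finite(tot) & tot != 0
  theta <- if (any(usable)) sum(comp$a[usable]) / sum(tot[usable]) else NaN
  structure(theta, n_loci = sum(usable), n_excluded = sum(!usable))
}
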