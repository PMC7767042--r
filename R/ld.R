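# Two-locus linkage disequilibrium from unphased genotypes by EM
# maximum likelihood. Of the nine two-locus genotype classes only the
# double heterozygote is phase-ambiguous; the E-step splits it between the
# coupling (AB/ab) and repulsion (Ab/aB) phases in proportion to the
# current haplotype-product probabilities. All EM iterates keep haplotype
# margins equal to the sample allele frequencies, so only the phase split
# is estimated.

# 3x3 genotype-pair count table from two dosage vectors (complete cases).
pair_counts <- function(gA, gB) {
  keep <- !is.na(gA) & !is.na(gB)
  matrix(tabulate(3L * gA[keep] + gB[keep] + 1L, nbins = 9L),
         nrow = 3L, byrow = TRUE)  # rows gA = 0..2, cols gB = 0..2
}

# Multinomial log-likelihood of genotype classes given haplotype freqs
# f = c(h11, h10, h01, h00) (first index = alt at locus A).
ld_loglik <- function(n, f) {
  h11 <- f[1]; h10 <- f[2]; h01 <- f[3]; h00 <- f[4]
  P <- matrix(c(h00^2,        2 * h00 * h01,            h01^2,
                2 * h00 * h10, 2 * (h11 * h00 + h10 * h01), 2 * h01 * h11,
                h10^2,        2 * h10 * h11,            h11^2),
              nrow = 3L, byrow = TRUE)
  use <- n > 0
  if (any(P[use] <= 0)) return(-Inf)
  sum(n[use] * log(P[use]))
}

# Core EM on a 3x3 count table. init_w = initial coupling fraction for the
# double heterozygotes.
em_core <- function(n, init_w, tol, max_iter) {
  N2 <- 2 * sum(n)
  c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  c01 <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  c00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  ndh <- n[2, 2]
  w <- init_w
  f <- c(c11 + ndh * w, c10 + ndh * (1 - w),
         c01 + ndh * (1 - w), c00 + ndh * w) / N2
  ll <- ld_loglik(n, f)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (ndh > 0) {
      coup <- f[1] * f[4]; rep_ <- f[2] * f[3]
      w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    }
    f_new <- c(c11 + ndh * w, c10 + ndh * (1 - w),
               c01 + ndh * (1 - w), c00 + ndh * w) / N2
    ll_new <- ld_loglik(n, f_new)
    stopifnot(ll_new >= ll - 1e-9)  # EM ascent property
    f <- f_new
    if (ll_new - ll < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  list(f = f, loglik = ll, iterations = iter, converged = converged)
}

#' EM haplotype frequencies and r2 for a pair of loci
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased diploid
#' genotypes within one taxon, with D, D', and r2 derived from them. The
#' first restart starts at linkage equilibrium; the remaining restarts use
#' random phase splits to escape the saddle that equilibrium initialization
#' can sit on (e.g. when every individual is doubly heterozygous, where two
#' symmetric maxima exist and the higher-|D| one is reported with
#' `multimodal = TRUE`).
#'
#' @param x a `genotype_matrix`.
#' @param taxon taxon label.
#' @param locusA,locusB locus ids or column indices.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of EM starts (>= 1).
#' @param min_n minimum pairwise-complete individuals; below it the
#'   estimate is `NaN` with `ok = FALSE`.
#' @return list: `locusA`, `locusB`, `hap_freq` (p_AB, p_Ab, p_aB, p_ab
#'   with "A"/"B" the alt alleles), `D`, `Dprime`, `r2`, `loglik`,
#'   `iterations`, `converged`, `multimodal`, `n`, `ok`.
#' @export
em_haplotype_frequencies <- function(x, taxon, locusA, locusB, tol = 1e-8,
                                     max_iter = 1000L, n_restarts = 5L,
                                     min_n = 5L) {
  jA <- if (is.character(locusA)) match(locusA, x$snps$id) else locusA
  jB <- if (is.character(locusB)) match(locusB, x$snps$id) else locusB
  g <- taxon_calls(x, taxon)
  est <- em_ld_pair(g[, jA], g[, jB], tol = tol, max_iter = max_iter,
                    n_restarts = n_restarts, min_n = min_n)
  c(list(locusA = x$snps$id[jA], locusB = x$snps$id[jB]), est)
}

# Workhorse on two dosage vectors; shared with ld_summary().
em_ld_pair <- function(gA, gB, tol = 1e-8, max_iter = 1000L,
                       n_restarts = 5L, min_n = 5L) {
  n <- pair_counts(gA, gB)
  N <- sum(n)
  bad <- function(reason) list(hap_freq = rep(NaN, 4), D = NaN, Dprime = NaN,
                               r2 = NaN, loglik = NA_real_, iterations = 0L,
                               converged = FALSE, multimodal = FALSE,
                               n = N, ok = FALSE, reason = reason)
  if (N < min_n) return(bad("too few pairwise-complete individuals"))
  pA <- (2 * sum(n[3, ]) + sum(n[2, ])) / (2 * N)
  pB <- (2 * sum(n[, 3]) + sum(n[, 2])) / (2 * N)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(bad("monomorphic locus"))
  inits <- c(0.5, runif(max(0L, n_restarts - 1L)))
  fits <- lapply(inits, function(w0) em_core(n, w0, tol, max_iter))
  lls <- vapply(fits, `[[`, 0, "loglik")
  Ds <- vapply(fits, function(fit) fit$f[1] - pA * pB, 0)
  best_ll <- max(lls)
  near <- which(lls >= best_ll - 1e-6)
  multimodal <- length(unique(round(Ds[near], 4))) > 1L
  # among near-optimal solutions prefer the higher-|D| one (tie convention)
  pick <- near[which.max(abs(Ds[near]))]
  fit <- fits[[pick]]
  f <- fit$f
  D <- f[1] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(hap_freq = setNames(f[c(1, 2, 3, 4)],
                           c("p_AB", "p_Ab", "p_aB", "p_ab")),
       D = D, Dprime = if (dmax > 0) abs(D) / dmax else NaN, r2 = r2,
       loglik = fit$loglik, iterations = fit$iterations,
       converged = fit$converged, multimodal = multimodal, n = N, ok = TRUE,
       reason = NA_character_)
}

#' Within-/between-gene LD threshold summary
#'
#' Computes EM r2 for all unordered pairs of gene-assigned SNPs within one
#' taxon, partitions pairs into within-gene (identical `gene_id`) and
#' between-gene, and reports for each partition the proportion of pairs
#' whose r2 exceeds each threshold. The denominator counts only pairs with
#' a defined r2; pairs with undefined r2 (monomorphic locus, too little
#' data) are tallied separately.
#'
#' @param x a `genotype_matrix` whose SNP table has `gene_id` assigned.
#' @param taxon taxon label.
#' @param thresholds numeric thresholds on r2.
#' @param max_pairs optional cap: when the number of pairs in a partition
#'   exceeds it, a simple random subsample of pairs is summarized
#'   (seeded by the caller's RNG state).
#' @return list: `summary` (data.frame: partition, threshold, proportion,
#'   n_pairs, n_undefined), `pairs` (per-pair data.frame with r2).
#' @export
ld_summary <- function(x, taxon, thresholds = c(0.5, 0.8, 0.95),
                       max_pairs = Inf) {
  keep <- !is.na(x$snps$gene_id)
  if (sum(keep) < 2L) stop("need >= 2 SNPs with gene assignments")
  sub <- subset_genotypes(x, loci = which(keep))
  L <- ncol(sub$calls)
  idx <- t(combn(L, 2L))
  same_gene <- sub$snps$gene_id[idx[, 1]] == sub$snps$gene_id[idx[, 2]]
  sel <- seq_len(nrow(idx))
  if (nrow(idx) > max_pairs) sel <- sort(sample(sel, max_pairs))
  g <- taxon_calls(sub, taxon)
  r2 <- vapply(sel, function(k)
    em_ld_pair(g[, idx[k, 1]], g[, idx[k, 2]])$r2, 0)
  pairs <- data.frame(locusA = sub$snps$id[idx[sel, 1]],
                      locusB = sub$snps$id[idx[sel, 2]],
                      same_gene = same_gene[sel], r2 = r2,
                      stringsAsFactors = FALSE)
  summarize_partition <- function(part, label) {
    vals <- pairs$r2[part]
    defined <- vals[is.finite(vals)]
    do.call(rbind, lapply(thresholds, function(th)
      data.frame(partition = label, threshold = th,
                 proportion = if (length(defined)) mean(defined > th) else NaN,
                 n_pairs = length(defined),
                 n_undefined = sum(!is.finite(vals)))))
  }
  summary <- rbind(summarize_partition(pairs$same_gene, "within_gene"),
                   summarize_partition(!pairs$same_gene, "between_gene"))
  list(summary = summary, pairs = pairs)
}
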