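# Independent oracle implementations used to cross-check the package code.
# These are deliberately written as plain, loop-based textbook
# transcriptions, separate from the vectorized implementations in R/.

# --- Weir & Cockerham (1984) per-locus components, scalar transcription --
# n, p, h: per-population sample sizes (diploids), alt-allele frequencies,
# observed heterozygote proportions.
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Components from raw per-population genotype count triples (n0, n1, n2).
wc_oracle_counts <- function(counts) {
  n <- sapply(counts, sum)
  p <- sapply(counts, function(x) (x[2] + 2 * x[3]) / (2 * sum(x)))
  h <- sapply(counts, function(x) x[2] / sum(x))
  wc_oracle(n, p, h)
}

# --- Pearson chi-square, hand formula ------------------------------------
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# --- Brute-force two-locus haplotype MLE ----------------------------------
# Genotype-class probabilities written out independently of the package.
bf_class_probs <- function(h11, h10, h01, h00) {
  matrix(c(h00^2,         2 * h00 * h01,                h01^2,
           2 * h00 * h10, 2 * (h11 * h00 + h10 * h01),  2 * h01 * h11,
           h10^2,         2 * h10 * h11,                h11^2),
         nrow = 3, byrow = TRUE)
}

bf_loglik <- function(counts, h11, h10, h01, h00) {
  P <- bf_class_probs(h11, h10, h01, h00)
  use <- counts > 0
  if (any(P[use] <= 0)) return(-Inf)
  sum(counts[use] * log(P[use]))
}

# Maximize over haplotype frequencies by a dense grid over D at the sample
# allele-frequency margins (where the two-locus multinomial MLE lies),
# refined by optimize(); a softmax Nelder-Mead search over the full simplex
# double-checks that no off-margin point does better.
bf_hap_mle <- function(gA, gB, grid_n = 4001) {
  keep <- !is.na(gA) & !is.na(gB)
  gA <- gA[keep]; gB <- gB[keep]
  counts <- matrix(0, 3, 3)
  for (i in seq_along(gA)) counts[gA[i] + 1, gB[i] + 1] <-
      counts[gA[i] + 1, gB[i] + 1] + 1
  N <- length(gA)
  pA <- sum(gA) / (2 * N); pB <- sum(gB) / (2 * N)
  D_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  D_hi <- min(pA * (1 - pB), (1 - pA) * pB)
  # the margin-preserving family, written explicitly
  hap_of_D <- function(D) c(pA * pB + D, pA * (1 - pB) - D,
                            (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D)
  ll_of_D <- function(D) do.call(bf_loglik, c(list(counts), as.list(hap_of_D(D))))
  Ds <- seq(D_lo, D_hi, length.out = grid_n)
  lls <- vapply(Ds, ll_of_D, 0)
  best <- which.max(lls)
  lo <- Ds[max(1, best - 1)]; hi <- Ds[min(grid_n, best + 1)]
  opt <- optimize(ll_of_D, c(lo, hi), maximum = TRUE, tol = 1e-12)
  cand <- if (opt$objective > lls[best]) list(D = opt$maximum, ll = opt$objective)
          else list(D = Ds[best], ll = lls[best])
  # full-simplex check via softmax parametrization
  nm_ll <- -Inf
  for (rep in 1:5) {
    par0 <- rnorm(3)
    fit <- optim(par0, function(par) {
      e <- exp(c(par, 0)); f <- e / sum(e)
      -bf_loglik(counts, f[1], f[2], f[3], f[4])
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
    nm_ll <- max(nm_ll, -fit$value)
  }
  f <- hap_of_D(cand$D)
  D <- f[1] - pA * pB
  r2 <- if (pA %in% c(0, 1) || pB %in% c(0, 1)) NaN
        else D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(hap = f, loglik = max(cand$ll, nm_ll), loglik_margin = cand$ll,
       D = D, r2 = r2, pA = pA, pB = pB)
}

# --- Small fixture builders ----------------------------------------------
# genotype_matrix from per-taxon genotype count triples (n0, n1, n2) at a
# single locus; counts is a named list taxon -> c(n0, n1, n2).
gm_from_counts <- function(counts, locus_id = "locus1") {
  calls <- unlist(lapply(counts, function(x) rep(0:2, times = x)))
  taxon <- rep(names(counts), times = sapply(counts, sum))
  genotype_matrix(matrix(as.integer(calls), ncol = 1), taxon,
                  data.frame(id = locus_id, chrom = "un", pos = 1,
                             ref = "A", alt = "T"))
}

# Table-2-style genotype distributions (individuals per genotype class),
# as printed for the three flagged SNPs: columns coluzzii, bamako, savanna.
table2_counts <- list(
  "MAP2K4-164" = list(coluzzii = c(164, 1, 0), bamako = c(13, 74, 87),
                      savanna = c(58, 27, 1)),
  "Raf-784" = list(coluzzii = c(22, 75, 55), bamako = c(128, 3, 0),
                   savanna = c(82, 0, 0)),
  "Raf-851" = list(coluzzii = c(12, 78, 60), bamako = c(2, 20, 106),
                   savanna = c(69, 2, 3)))

# Random small genotype matrix (2 loci) for EM cross-checks.
random_two_locus_gm <- function(n_max = 12) {
  n <- sample(5:n_max, 1)
  repeat {
    calls <- cbind(rbinom(n, 2, runif(1, 0.2, 0.8)),
                   rbinom(n, 2, runif(1, 0.2, 0.8)))
    if (all(colSums(calls) > 0) && all(colSums(2 - calls) > 0)) break
  }
  genotype_matrix(matrix(as.integer(calls), ncol = 2), rep("t", n),
                  data.frame(id = c("A", "B"), chrom = "un", pos = 1:2,
                             ref = "A", alt = "T"))
}
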