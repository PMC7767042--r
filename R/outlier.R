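# F_ST outlier scan against a hierarchical-island coalescent null
# (FDIST-style): simulate the joint null distribution of (within-deme
# heterozygosity, W&C theta), bin it by heterozygosity, and rank each
# observed locus's theta within its bin to get an upper-tail selection
# p-value.

#' Configuration of the hierarchical-island null model
#'
#' Demes are arranged in groups; migration is commoner within than between
#' groups (`M_w > M_b`), which lowers the neutral F_ST variance relative to
#' a flat island model and thereby reduces false-positive outliers.
#'
#' @param n_groups number of groups.
#' @param demes_per_group demes in each group.
#' @param M_w,M_b scaled migration rates within / between groups
#'   (`M_w > M_b > 0`); each lineage migrates at total rate
#'   `(M_w + M_b) / 2`.
#' @param sample_groups group (1-based) of each sampled deme; one sampled
#'   deme per entry, each placed in a distinct deme.
#' @param sample_sizes diploid individuals sampled per deme; defaults mimic
#'   the three-taxon whole-genome design (12/11/13).
#' @param n_sims number of simulated loci (>= 100).
#' @return a validated `hier_island_config` list.
#' @export
hier_island_config <- function(n_groups = 10L, demes_per_group = 100L,
                               M_w = 20, M_b = 2,
                               sample_groups = c(1L, 2L, 3L),
                               sample_sizes = c(12L, 11L, 13L),
                               n_sims = 20000L) {
  stopifnot(M_w > M_b, M_b > 0,
            length(sample_groups) == length(sample_sizes),
            all(sample_groups >= 1), all(sample_groups <= n_groups),
            all(sample_sizes >= 1), n_sims >= 100,
            n_groups >= 1, demes_per_group >= 1)
  counts <- table(sample_groups)
  if (any(counts > demes_per_group))
    stop("more sampled demes in a group than the group has demes")
  cfg <- list(n_groups = as.integer(n_groups),
              demes_per_group = as.integer(demes_per_group),
              M_w = M_w, M_b = M_b,
              sample_groups = as.integer(sample_groups),
              sample_sizes = as.integer(sample_sizes),
              n_sims = as.integer(n_sims))
  class(cfg) <- "hier_island_config"
  cfg
}

# Distinct deme index (0-based) for each sampled deme: successive demes
# within each requested group.
sampled_deme_indices <- function(cfg) {
  within_rank <- stats::ave(seq_along(cfg$sample_groups), cfg$sample_groups,
                            FUN = seq_along) - 1L
  (cfg$sample_groups - 1L) * cfg$demes_per_group + within_rank
}

#' Simulate the hierarchical-island neutral null
#'
#' One structured-coalescent genealogy per locus, one mutation placed
#' proportionally to branch length, genotypes formed by random pairing of
#' gene copies within each sampled deme. Heterozygosity is the mean over
#' demes of the within-deme expected heterozygosity 2p(1-p); theta is the
#' W&C estimator across sampled demes.
#'
#' @param config a [hier_island_config()].
#' @param seed optional integer seed.
#' @return data.frame: `het`, `theta`, `tmrca`, `total_length`, plus
#'   per-deme derived counts as attribute `"derived"`.
#' @export
simulate_hier_island_null <- function(config, seed = NULL) {
  stopifnot(inherits(config, "hier_island_config"))
  if (!is.null(seed)) set.seed(seed)
  sim <- hier_island_sim_cpp(config$n_sims, config$n_groups,
                             config$demes_per_group, config$M_w, config$M_b,
                             sampled_deme_indices(config),
                             config$sample_sizes)
  n <- matrix(config$sample_sizes, nrow = config$n_sims,
              ncol = length(config$sample_sizes), byrow = TRUE)
  p <- sim$derived / (2 * n)
  h <- sim$hets / n
  het <- rowMeans(2 * p * (1 - p))
  comp <- wc_components(n, p, h)
  tot <- comp$a + comp$b + comp$c
  out <- data.frame(het = het,
                    theta = ifelse(is.na(tot) | tot == 0, NaN, comp$a / tot),
                    tmrca = sim$tmrca, total_length = sim$total_length)
  attr(out, "derived") <- sim$derived
  out
}

# Heterozygosity quantile bins over the null, merging bins until each holds
# at least min_per_bin points. Returns break vector (inclusive lower -Inf).
het_bin_breaks <- function(null_het, n_bins, min_per_bin = 20L) {
  breaks <- unique(quantile(null_het, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  repeat {
    counts <- table(cut(null_het, breaks))
    small <- which(counts < min_per_bin)
    if (!length(small) || length(breaks) <= 2) break
    j <- small[1]
    drop <- if (j == length(counts)) j else j + 1L  # merge with neighbor
    breaks <- breaks[-drop]
  }
  breaks
}

#' Per-locus outlier p-values conditioned on heterozygosity
#'
#' Null (het, theta) points are binned by heterozygosity quantiles; each
#' observed locus is ranked against the null thetas of its own bin:
#' p = (1 + #\{null theta >= observed theta\}) / (n_bin + 1).
#'
#' @param observed data.frame with columns `locus`, `het`, `theta`.
#' @param null data.frame from [simulate_hier_island_null()] (columns
#'   `het`, `theta`).
#' @param n_het_bins number of heterozygosity quantile bins (bins with
#'   fewer than 20 null points are merged).
#' @return data.frame: locus, theta, het, bin, n_bin, p_value.
#' @export
outlier_pvalues <- function(observed, null, n_het_bins = 20L) {
  keep <- is.finite(null$theta) & is.finite(null$het)
  if (!any(keep)) stop("empty null distribution")
  null <- null[keep, , drop = FALSE]
  breaks <- het_bin_breaks(null$het, n_het_bins)
  null_bin <- findInterval(null$het, breaks, rightmost.closed = TRUE)
  obs_bin <- findInterval(observed$het, breaks, rightmost.closed = TRUE)
  obs_bin <- pmin(pmax(obs_bin, 1L), length(breaks) - 1L)
  p <- numeric(nrow(observed))
  n_bin <- integer(nrow(observed))
  for (b in unique(obs_bin)) {
    nt <- null$theta[null_bin == b]
    sel <- obs_bin == b
    n_bin[sel] <- length(nt)
    p[sel] <- vapply(observed$theta[sel],
                     function(th) (1 + sum(nt >= th)) / (length(nt) + 1), 0)
  }
  undefined <- !is.finite(observed$theta)
  p[undefined] <- NA_real_
  data.frame(locus = observed$locus, theta = observed$theta,
             het = observed$het, bin = obs_bin, n_bin = n_bin, p_value = p,
             stringsAsFactors = FALSE)
}

#' Flag outlier loci after Bonferroni correction
#'
#' @param results data.frame from [outlier_pvalues()].
#' @param alpha family-wise level.
#' @param m number of scanned loci (defaults to rows of `results`).
#' @return `results` with a logical `flagged` column; the threshold
#'   `alpha/m` is attached as attribute `"threshold"`.
#' @export
flag_outliers <- function(results, alpha = 0.05, m = nrow(results)) {
  adj <- bonferroni_adjust(results$p_value, m = m, alpha = alpha)
  results$flagged <- adj$significant
  attr(results, "threshold") <- adj$threshold
  results
}

#' Observed (het, theta) table for an outlier scan
#'
#' Convenience extractor pairing each locus's W&C theta across the chosen
#' taxa with its mean within-taxon expected heterozygosity, the two
#' coordinates the null scan conditions on.
#'
#' @param x a `genotype_matrix`.
#' @param taxa_subset taxa to include.
#' @return data.frame: locus, het, theta.
#' @export
observed_scan_stats <- function(x, taxa_subset = taxa(x)) {
  inp <- wc_inputs(x, taxa_subset)
  comp <- wc_components(inp$n, inp$p, inp$h)
  tot <- comp$a + comp$b + comp$c
  het <- rowMeans(2 * inp$p * (1 - inp$p))
  data.frame(locus = x$snps$id,
             het = het,
             theta = ifelse(is.na(tot) | tot == 0, NaN, comp$a / tot),
             stringsAsFactors = FALSE)
}
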