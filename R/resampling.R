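# Gene-set resampling tests. Genes (not SNPs) are the resampling unit, so
# within-gene LD is preserved under the null. Empirical p-values use the
# add-one convention (1 + #{null >= observed}) / (B + 1) and can never be
# zero; exhaustive enumeration over all subsets is available for small
# pools, where the exact upper-tail fraction is reported instead.

new_resampling_result <- function(observed, null, seed, method = "sampled") {
  B <- length(null)
  p <- if (method == "exhaustive") mean(null >= observed)
       else (1 + sum(null >= observed)) / (B + 1)
  structure(list(observed = observed, null = null, null_mean = mean(null),
                 null_sd = sd(null), null_sem = sd(null) / sqrt(B),
                 p_value = p, B = B, seed = seed, method = method),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling test (%s, B = %d): observed = %.4g, null = %.4g +/- %.4g (SEM %.4g), p = %.4g\n",
              x$method, x$B, x$observed, x$null_mean, x$null_sd, x$null_sem,
              x$p_value))
  invisible(x)
}

# Engine: observed statistic of the focal gene set vs the statistic of
# random equal-sized sets. gene_ids = full pool of genes; stat_fun(ids)
# returns a scalar. pool = "non_focal" samples only non-focal genes,
# "all" samples from every gene.
resample_gene_sets <- function(gene_ids, focal_ids, stat_fun, B = 1000L,
                               seed = NULL, pool = c("non_focal", "all"),
                               exhaustive = FALSE) {
  pool <- match.arg(pool)
  focal_ids <- intersect(focal_ids, gene_ids)
  if (!length(focal_ids)) stop("focal gene set is empty (after exclusions)")
  candidates <- if (pool == "all") gene_ids else setdiff(gene_ids, focal_ids)
  k <- length(focal_ids)
  if (length(candidates) < k)
    stop("candidate pool smaller than the focal set")
  observed <- stat_fun(focal_ids)
  if (exhaustive) {
    if (choose(length(candidates), k) > 1e5)
      stop("pool too large for exhaustive enumeration")
    subsets <- combn(candidates, k, simplify = FALSE)
    null <- vapply(subsets, stat_fun, 0)
    return(new_resampling_result(observed, null, seed, "exhaustive"))
  }
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(B), function(b)
    stat_fun(sample(candidates, k)), 0)
  new_resampling_result(observed, null, seed)
}

# Drop genes overlapping any exclusion region (e.g. speciation islands).
apply_gene_exclusions <- function(genes, exclude_bed) {
  if (is.null(exclude_bed) || nrow(exclude_bed) == 0) return(genes)
  hits <- GenomicRanges::findOverlaps(bed_as_granges(genes),
                                      bed_as_granges(exclude_bed))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) genes <- genes[-drop, , drop = FALSE]
  genes
}

# Per-gene sums of W&C components (and SNP counts) for a taxa contrast.
gene_component_table <- function(x, taxa_subset, genes,
                                 assignments = snp_gene_assignments(x)) {
  comp <- wc_fst_all_loci(x, taxa_subset)
  m <- merge(assignments, comp, by.x = "snp_id", by.y = "locus")
  tot <- m$a + m$b + m$c
  usable <- is.finite(tot) & tot != 0
  agg <- function(v) tapply(v, m$gene_id, sum)
  sums_a <- agg(ifelse(usable, m$a, 0))
  sums_tot <- agg(ifelse(usable, tot, 0))
  n_snps <- agg(rep(1, nrow(m)))
  out <- data.frame(gene_id = genes$gene_id, sum_a = 0, sum_tot = 0,
                    n_snps = 0, stringsAsFactors = FALSE)
  idx <- match(names(sums_a), out$gene_id)
  ok <- !is.na(idx)
  out$sum_a[idx[ok]] <- sums_a[ok]
  out$sum_tot[idx[ok]] <- sums_tot[ok]
  out$n_snps[idx[ok]] <- n_snps[ok]
  out
}

#' Gene-set F_ST bootstrap test
#'
#' Tests whether the multilocus (ratio-of-sums) Weir-Cockerham F_ST of the
#' immune gene set exceeds what random equal-sized sets of non-immune genes
#' show, for one pair (or larger subset) of taxa. Genes inside the supplied
#' exclusion regions (e.g. speciation islands) are removed from both the
#' immune set and the sampling pool before anything is computed.
#'
#' @param x a `genotype_matrix` with gene-assigned SNPs
#'   ([assign_snps_to_genes()]).
#' @param taxa_pair taxa to contrast.
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, optional `immune`).
#' @param immune_gene_ids immune set; defaults to `genes$gene_id[genes$immune]`.
#' @param B number of random gene sets.
#' @param seed integer seed (NULL = use current RNG state).
#' @param exclude_bed optional BED-style data.frame of exclusion regions.
#' @param pool `"non_focal"` (default; random sets drawn from non-immune
#'   genes) or `"all"`.
#' @param exhaustive enumerate all subsets instead of sampling (small pools
#'   only); the reported p is then the exact upper-tail fraction.
#' @return a `resampling_result` (upper-tail add-one empirical p).
#' @export
geneset_fst_test <- function(x, taxa_pair, genes, immune_gene_ids = NULL,
                             B = 1000L, seed = NULL, exclude_bed = NULL,
                             pool = "non_focal", exhaustive = FALSE) {
  if (is.null(immune_gene_ids)) immune_gene_ids <- genes$gene_id[genes$immune]
  genes <- apply_gene_exclusions(genes, exclude_bed)
  immune_gene_ids <- intersect(immune_gene_ids, genes$gene_id)
  tab <- gene_component_table(x, taxa_pair, genes)
  stat_fun <- function(ids) {
    rows <- match(ids, tab$gene_id)
    s <- sum(tab$sum_tot[rows])
    if (s == 0) return(NaN)
    sum(tab$sum_a[rows]) / s
  }
  resample_gene_sets(tab$gene_id, immune_gene_ids, stat_fun, B = B,
                     seed = seed, pool = pool, exhaustive = exhaustive)
}

#' Gene-set SNP-count bootstrap test
#'
#' Tests whether more SNPs fall in the immune gene set than in random
#' equal-sized gene sets. The statistic is the number of SNP-gene
#' assignments within the set (a SNP inside two member genes counts per
#' gene).
#'
#' @inheritParams geneset_fst_test
#' @param snp_assignments data.frame (`snp_id`, `gene_id`) from
#'   [snp_gene_assignments()], or a `genotype_matrix`.
#' @param pool `"all"` (default): random sets drawn from the full gene pool.
#' @return a `resampling_result`; `null_sem` = null SD / sqrt(B).
#' @export
geneset_snpcount_test <- function(snp_assignments, genes,
                                  immune_gene_ids = NULL, B = 1000L,
                                  seed = NULL, exclude_bed = NULL,
                                  pool = "all", exhaustive = FALSE) {
  if (inherits(snp_assignments, "genotype_matrix"))
    snp_assignments <- snp_gene_assignments(snp_assignments)
  if (is.null(immune_gene_ids)) immune_gene_ids <- genes$gene_id[genes$immune]
  genes <- apply_gene_exclusions(genes, exclude_bed)
  immune_gene_ids <- intersect(immune_gene_ids, genes$gene_id)
  counts <- table(snp_assignments$gene_id)
  n_snps <- setNames(rep(0, nrow(genes)), genes$gene_id)
  n_snps[names(counts)[names(counts) %in% genes$gene_id]] <-
    as.numeric(counts[names(counts) %in% genes$gene_id])
  stat_fun <- function(ids) sum(n_snps[ids])
  resample_gene_sets(genes$gene_id, immune_gene_ids, stat_fun, B = B,
                     seed = seed, pool = pool, exhaustive = exhaustive)
}

#' Inversion-overlap permutation test
#'
#' A gene "hits" an inversion when its interval overlaps the inversion or
#' lies within `near_distance` of an inversion boundary. The observed
#' statistic is the number of immune genes hitting; the null redraws gene
#' sets of the same size uniformly from all genes.
#'
#' @inheritParams geneset_fst_test
#' @param inversions inversion data.frame (`name`, `chrom`, `start`, `end`).
#' @param near_distance maximum gap (bp) between gene and inversion for a
#'   near-hit; default 1 Mb.
#' @param chromosomes optional chromosome subset: restrict both the immune
#'   count and the sampling pool to genes on these chromosomes (e.g. "2R").
#'   Default genome-wide.
#' @return a `resampling_result` with `null_mean`, `null_sd` and the
#'   upper-tail p.
#' @export
inversion_overlap_test <- function(genes, immune_gene_ids = NULL, inversions,
                                   near_distance = 1e6, B = 1000L,
                                   seed = NULL, chromosomes = NULL,
                                   pool = "all", exhaustive = FALSE) {
  if (is.null(inversions) || nrow(inversions) == 0)
    stop("no inversions supplied")
  if (is.null(immune_gene_ids)) immune_gene_ids <- genes$gene_id[genes$immune]
  if (!is.null(chromosomes)) {
    genes <- genes[genes$chrom %in% chromosomes, , drop = FALSE]
    immune_gene_ids <- intersect(immune_gene_ids, genes$gene_id)
  }
  hit <- gene_inversion_hits(genes, inversions, near_distance)
  names(hit) <- genes$gene_id
  stat_fun <- function(ids) sum(hit[ids])
  resample_gene_sets(genes$gene_id, immune_gene_ids, stat_fun, B = B,
                     seed = seed, pool = pool, exhaustive = exhaustive)
}

#' Which genes hit an inversion (overlap or within `near_distance`)
#' @inheritParams inversion_overlap_test
#' @return logical vector along `genes`.
#' @export
gene_inversion_hits <- function(genes, inversions, near_distance = 1e6) {
  gg <- bed_as_granges(genes)
  ii <- bed_as_granges(inversions)
  d <- GenomicRanges::distanceToNearest(gg, ii)
  out <- rep(FALSE, nrow(genes))
  qh <- S4Vectors::queryHits(d)
  out[qh] <- S4Vectors::elementMetadata(d)$distance <= near_distance
  out
}
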