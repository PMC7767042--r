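# Synthetic-data generators reproducing the statistical structure the
# analysis assumes: Balding-Nichols allele-frequency divergence among taxa
# (so the generating F maps directly onto the W&C estimand), Hardy-Weinberg
# genotypes within taxa, optional within-gene LD blocks, and a genome-scale
# annotation with an immune gene subset and chromosome-2R inversions.

#' Balding-Nichols genotype simulation
#'
#' Per locus, an ancestral frequency p is drawn (default Uniform(0.05,
#' 0.95)); each taxon's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), and
#' individual genotypes are Binomial(2, taxon frequency) — Hardy-Weinberg
#' within taxon. The expected W&C F_ST across taxa equals F. Loci that land
#' monomorphic in every taxon are retained (downstream code must handle
#' them).
#'
#' @param n_per_taxon named integer vector: diploid individuals per taxon.
#' @param n_loci number of loci.
#' @param F_values per-locus Balding-Nichols F, recycled to `n_loci`;
#'   values must be in (0, 1) (values below 1e-9 are treated as F = 0, i.e.
#'   no divergence).
#' @param ancestral_freq_sampler function(n) returning n ancestral
#'   frequencies; default Uniform(0.05, 0.95).
#' @param snps optional SNP annotation table (see [genotype_matrix()]);
#'   default loci on pseudo-chromosome "un" at positions 1..L.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with the per-taxon generating frequencies
#'   attached as attribute `"taxon_freq"`.
#' @export
gen_balding_nichols <- function(n_per_taxon, n_loci, F_values,
                                ancestral_freq_sampler = NULL, snps = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_per_taxon)))
    names(n_per_taxon) <- paste0("taxon", seq_along(n_per_taxon))
  Fv <- rep_len(F_values, n_loci)
  stopifnot(all(Fv >= 0), all(Fv < 1))
  if (is.null(ancestral_freq_sampler))
    ancestral_freq_sampler <- function(n) runif(n, 0.05, 0.95)
  p0 <- ancestral_freq_sampler(n_loci)
  K <- length(n_per_taxon)
  freq <- matrix(0, n_loci, K, dimnames = list(NULL, names(n_per_taxon)))
  pos <- Fv > 1e-9
  for (k in seq_len(K)) {
    freq[!pos, k] <- p0[!pos]
    if (any(pos))
      freq[pos, k] <- rbeta(sum(pos), p0[pos] * (1 - Fv[pos]) / Fv[pos],
                            (1 - p0[pos]) * (1 - Fv[pos]) / Fv[pos])
  }
  calls <- matrix(NA_integer_, sum(n_per_taxon), n_loci)
  row0 <- 0L
  for (k in seq_len(K)) {
    nk <- n_per_taxon[[k]]
    calls[row0 + seq_len(nk), ] <-
      matrix(rbinom(nk * n_loci, 2L, rep(freq[, k], each = nk)),
             nrow = nk)
    row0 <- row0 + nk
  }
  if (is.null(snps))
    snps <- data.frame(id = paste0("snp", seq_len(n_loci)), chrom = "un",
                       pos = seq_len(n_loci), ref = "A", alt = "T",
                       stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, taxon = rep(names(n_per_taxon), n_per_taxon),
                        snps = snps)
  attr(gm, "taxon_freq") <- freq
  attr(gm, "ancestral_freq") <- p0
  gm
}

# Haplotype frequencies (h11, h10, h01, h00) achieving r2 = target at
# allele frequencies pA, pB (positive-D solution). Errors naming the
# feasible maximum when the target is out of reach.
solve_hap_freqs <- function(r2_target, pA, pB) {
  stopifnot(r2_target >= 0, r2_target <= 1, pA > 0, pA < 1, pB > 0, pB < 1)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  D_max <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- sqrt(r2_target * denom)
  if (D > D_max + 1e-12) {
    stop(sprintf(
      "r2 target %.3f infeasible at freqs (%.3f, %.3f); feasible maximum is %.3f",
      r2_target, pA, pB, D_max^2 / denom))
  }
  c(h11 = pA * pB + D, h10 = pA * (1 - pB) - D,
    h01 = (1 - pA) * pB - D, h00 = (1 - pA) * (1 - pB) + D)
}

#' Generate an unphased genotype block with target pairwise LD
#'
#' Haplotypes over `length(p)` loci are built as a Markov chain in which
#' each adjacent locus pair attains the target r2 exactly (in expectation)
#' at the given allele frequencies; more distant pairs have geometrically
#' decaying LD. Individuals pair two independent haplotype draws and are
#' returned as dosages.
#'
#' @param n_individuals diploid individuals.
#' @param block_r2_target target r2 for adjacent locus pairs, in [0, 1].
#' @param p per-locus alt-allele frequencies (length >= 2).
#' @param seed optional integer seed.
#' @return integer matrix `n_individuals x length(p)` of dosages; the
#'   adjacent-pair haplotype frequencies are attached as attribute
#'   `"hap_freq"` (first pair).
#' @export
gen_ld_block <- function(n_individuals, block_r2_target, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(p)
  stopifnot(L >= 2, n_individuals >= 1)
  n_hap <- 2L * n_individuals
  hap <- matrix(0L, n_hap, L)
  hap[, 1] <- rbinom(n_hap, 1L, p[1])
  first_pair <- NULL
  for (j in seq_len(L - 1L)) {
    f <- solve_hap_freqs(block_r2_target, p[j], p[j + 1])
    if (j == 1L) first_pair <- f
    # P(next = 1 | cur): conditional haplotype transition
    p1_given1 <- f["h11"] / p[j]
    p1_given0 <- f["h01"] / (1 - p[j])
    pr <- ifelse(hap[, j] == 1L, p1_given1, p1_given0)
    hap[, j + 1] <- rbinom(n_hap, 1L, pr)
  }
  calls <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
    hap[seq(2, n_hap, by = 2), , drop = FALSE]
  storage.mode(calls) <- "integer"
  attr(calls, "hap_freq") <- first_pair
  calls
}

#' Generate a genome annotation with an immune subset and inversions
#'
#' Genes of fixed length are placed without overlap, uniformly along each
#' chromosome (allocated proportionally to chromosome length). The immune
#' subset is drawn uniformly, or biased toward inversion-hitting genes.
#'
#' @param n_genes total genes.
#' @param chromosome_lengths named numeric vector (bp).
#' @param inversion_spec inversion data.frame (`name`, `chrom`, `start`,
#'   `end`) or `NULL` for the default five chromosome-2R paracentric
#'   inversions (j, b, c, d, u).
#' @param immune_count immune genes to designate.
#' @param immune_placement_bias in [0, 1]: fraction of the immune set drawn
#'   from inversion-hitting genes (0 = uniform; 1 = all hitting, capacity
#'   permitting).
#' @param gene_length gene interval length (bp).
#' @param near_distance hit distance passed to [gene_inversion_hits()].
#' @param seed optional integer seed.
#' @return list: `genes` (gene_id, chrom, start, end, immune),
#'   `inversions`, `immune_ids`.
#' @export
gen_annotation <- function(n_genes, chromosome_lengths = NULL,
                           inversion_spec = NULL, immune_count,
                           immune_placement_bias = 0, gene_length = 2000L,
                           near_distance = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chromosome_lengths))
    chromosome_lengths <- c(X = 24e6, `2R` = 61e6, `2L` = 49e6,
                            `3R` = 53e6, `3L` = 42e6)
  if (is.null(inversion_spec))
    inversion_spec <- data.frame(
      name = c("2Rj", "2Rb", "2Rc", "2Rd", "2Ru"),
      chrom = "2R",
      start = c(2e6, 18e6, 26e6, 32e6, 39e6),
      end = c(15e6, 25e6, 31e6, 36e6, 42e6),
      stringsAsFactors = FALSE)
  stopifnot(immune_count <= n_genes, immune_placement_bias >= 0,
            immune_placement_bias <= 1)
  alloc <- round(n_genes * chromosome_lengths / sum(chromosome_lengths))
  alloc[1] <- alloc[1] + n_genes - sum(alloc)
  genes_list <- lapply(seq_along(alloc), function(ci) {
    k <- alloc[ci]
    if (k == 0) return(NULL)
    len <- chromosome_lengths[ci]
    slack <- len - k * gene_length
    if (slack < 0) stop("cannot pack ", k, " genes of ", gene_length,
                        " bp into chromosome ", names(alloc)[ci])
    starts <- sort(floor(runif(k, 0, slack))) +
      (seq_len(k) - 1L) * gene_length
    data.frame(chrom = names(chromosome_lengths)[ci],
               start = as.integer(starts),
               end = as.integer(starts + gene_length),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, genes_list)
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end")]
  hit <- gene_inversion_hits(genes, inversion_spec, near_distance)
  n_from_hit <- min(round(immune_placement_bias * immune_count), sum(hit))
  immune_ids <- character(0)
  if (n_from_hit > 0)
    immune_ids <- sample(genes$gene_id[hit], n_from_hit)
  rest_pool <- setdiff(genes$gene_id, immune_ids)
  immune_ids <- c(immune_ids, sample(rest_pool, immune_count - n_from_hit))
  genes$immune <- genes$gene_id %in% immune_ids
  list(genes = genes, inversions = inversion_spec, immune_ids = immune_ids)
}

#' Study-mimic synthetic dataset configuration
#'
#' Defaults emulate the three-taxon *Anopheles* design: whole-genome-scale
#' sample sizes (12 Bamako, 11 Savanna, 13 coluzzii diploids), 12,519 genes
#' of which 231 form the immune set, immune-gene SNPs generated at
#' Balding-Nichols F = 0.13 and background SNPs at F = 0.035, Uniform(0.05,
#' 0.95) ancestral frequencies, and the five 2R inversions. Genotyping-scale
#' sample sizes (167/87/194) are available via `scale = "genotyping"`.
#'
#' @param taxa_n named integer vector of diploids per taxon; default per
#'   `scale`.
#' @param scale `"wgs"` or `"genotyping"` preset for `taxa_n`.
#' @param n_genes,immune_count genome size and immune subset size.
#' @param snps_per_gene SNPs per gene: a single integer or a function(n)
#'   returning per-gene counts (>= 1).
#' @param fst_immune,fst_background Balding-Nichols F for immune /
#'   background SNPs.
#' @param ld_block_r2 target within-gene adjacent-pair r2 (NULL or 0 for
#'   independent SNPs). LD blocks share one per-taxon frequency per gene.
#' @param ancestral_freq_sampler see [gen_balding_nichols()].
#' @param chromosome_lengths,inversion_spec,immune_placement_bias,gene_length
#'   see [gen_annotation()].
#' @param exclusion_bed optional speciation-island-style exclusion regions
#'   carried along for the gene-set tests.
#' @return a `study_mimic_config` list.
#' @export
study_mimic_config <- function(taxa_n = NULL, scale = c("wgs", "genotyping"),
                               n_genes = 12519L, immune_count = 231L,
                               snps_per_gene = 1L, fst_immune = 0.13,
                               fst_background = 0.035, ld_block_r2 = NULL,
                               ancestral_freq_sampler = NULL,
                               chromosome_lengths = NULL,
                               inversion_spec = NULL,
                               immune_placement_bias = 0,
                               gene_length = 2000L, exclusion_bed = NULL) {
  scale <- match.arg(scale)
  if (is.null(taxa_n))
    taxa_n <- if (scale == "wgs") c(bamako = 12L, savanna = 11L, coluzzii = 13L)
              else c(bamako = 167L, savanna = 87L, coluzzii = 194L)
  stopifnot(all(taxa_n >= 2), immune_count <= n_genes,
            fst_immune > 0, fst_immune < 1,
            fst_background > 0, fst_background < 1)
  structure(list(taxa_n = taxa_n, n_genes = as.integer(n_genes),
                 immune_count = as.integer(immune_count),
                 snps_per_gene = snps_per_gene, fst_immune = fst_immune,
                 fst_background = fst_background, ld_block_r2 = ld_block_r2,
                 ancestral_freq_sampler = ancestral_freq_sampler,
                 chromosome_lengths = chromosome_lengths,
                 inversion_spec = inversion_spec,
                 immune_placement_bias = immune_placement_bias,
                 gene_length = gene_length, exclusion_bed = exclusion_bed),
            class = "study_mimic_config")
}

#' Generate a full study-mimic dataset bundle
#'
#' Builds the annotation, places SNPs in genes, simulates Balding-Nichols
#' genotypes (immune genes at the immune F level, background genes at the
#' background level, optional within-gene LD blocks), and optionally writes
#' the bundle to disk in the package's external formats (VCF v4.2, taxon
#' TSV, gene/inversion BED4, immune-id list).
#'
#' @param config a [study_mimic_config()].
#' @param seed integer seed (generation is deterministic given it).
#' @param out_dir if non-NULL, write the file bundle here.
#' @return list: `genotypes` (gene-assigned [genotype_matrix()]), `genes`,
#'   `inversions`, `immune_ids`, `config`, and `paths` when written.
#' @export
gen_study_mimic <- function(config, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "study_mimic_config"))
  if (!is.null(seed)) set.seed(seed)
  ann <- gen_annotation(config$n_genes, config$chromosome_lengths,
                        config$inversion_spec, config$immune_count,
                        config$immune_placement_bias, config$gene_length)
  genes <- ann$genes
  n_snps_per_gene <- if (is.function(config$snps_per_gene))
    pmax(1L, as.integer(config$snps_per_gene(nrow(genes))))
  else rep(as.integer(config$snps_per_gene), nrow(genes))
  gene_idx <- rep(seq_len(nrow(genes)), n_snps_per_gene)
  L <- length(gene_idx)
  # SNP positions: distinct 1-based positions inside each gene interval
  offset <- unlist(lapply(n_snps_per_gene, function(k)
    sort(sample(config$gene_length, k))))
  pos <- genes$start[gene_idx] + offset  # BED start + 1..len = 1-based in gene
  snps <- data.frame(id = sprintf("%s_s%d", genes$gene_id[gene_idx],
                                  unlist(lapply(n_snps_per_gene, seq_len))),
                     chrom = genes$chrom[gene_idx], pos = as.integer(pos),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  Fv <- ifelse(genes$immune[gene_idx], config$fst_immune,
               config$fst_background)
  taxa_n <- config$taxa_n
  use_ld <- !is.null(config$ld_block_r2) && config$ld_block_r2 > 0
  if (!use_ld) {
    gm <- gen_balding_nichols(taxa_n, L, Fv,
                              ancestral_freq_sampler =
                                config$ancestral_freq_sampler,
                              snps = snps)
  } else {
    # one ancestral frequency per gene; within-gene SNPs share the taxon
    # frequency and are coupled into an LD block
    sampler <- config$ancestral_freq_sampler
    if (is.null(sampler)) sampler <- function(n) runif(n, 0.05, 0.95)
    p0 <- sampler(nrow(genes))
    Fg <- ifelse(genes$immune, config$fst_immune, config$fst_background)
    K <- length(taxa_n)
    freq <- matrix(rbeta(nrow(genes) * K,
                         rep(p0 * (1 - Fg) / Fg, K),
                         rep((1 - p0) * (1 - Fg) / Fg, K)),
                   ncol = K)
    calls <- matrix(NA_integer_, sum(taxa_n), L)
    col0 <- cumsum(c(0L, n_snps_per_gene))
    row0 <- cumsum(c(0L, unname(taxa_n)))
    for (gi in seq_len(nrow(genes))) {
      k_snps <- n_snps_per_gene[gi]
      jj <- col0[gi] + seq_len(k_snps)
      for (k in seq_len(K)) {
        f <- min(max(freq[gi, k], 1e-6), 1 - 1e-6)
        ii <- row0[k] + seq_len(taxa_n[k])
        calls[ii, jj] <- if (k_snps == 1L)
          rbinom(taxa_n[k], 2L, f)
        else gen_ld_block(taxa_n[k], config$ld_block_r2, rep(f, k_snps))
      }
    }
    gm <- genotype_matrix(calls, taxon = rep(names(taxa_n), taxa_n),
                          snps = snps)
  }
  gm <- assign_snps_to_genes(gm, genes)
  bundle <- list(genotypes = gm, genes = genes, inversions = ann$inversions,
                 immune_ids = ann$immune_ids, config = config)
  if (!is.null(out_dir)) bundle$paths <- write_study_bundle(bundle, out_dir)
  bundle
}

# Write a study bundle in the external-interface formats.
write_study_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    taxa = file.path(out_dir, "taxa.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    inversions = file.path(out_dir, "inversions.bed"),
    immune = file.path(out_dir, "immune_genes.txt"))
  write_vcf(bundle$genotypes, paths$vcf)
  write.table(data.frame(individual = bundle$genotypes$individuals,
                         taxon = bundle$genotypes$taxon),
              paths$taxa, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write_bed4(bundle$genes, paths$genes, name_col = "gene_id")
  write_bed4(bundle$inversions, paths$inversions)
  writeLines(bundle$immune_ids, paths$immune)
  paths
}
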