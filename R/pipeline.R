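# End-to-end orchestration: load or generate data, functional filter,
# per-locus popstats + association, pairwise F_ST per contrast, LD
# summaries, gene-set tests, inversion permutation, outlier scan. Each
# stage writes its TSV under out_dir and contributes to a summary JSON.
# Stages are individually re-runnable: every stage function consumes plain
# objects, this driver only wires them together.

#' Assemble a pipeline run configuration
#'
#' @param synthetic a [study_mimic_config()] to generate data, or `NULL`
#'   when reading from files.
#' @param vcf,taxon_table,genes_bed,inversions_bed,immune_list input paths
#'   (used when `synthetic` is NULL).
#' @param codon_usage optional codon-usage TSV path; when provided and the
#'   SNP table carries codon context, the functional filter is applied.
#' @param contrasts list of taxa character vectors to contrast; `NULL` =
#'   all pairs of observed taxa.
#' @param B resampling replicates for the gene-set and inversion tests.
#' @param alpha,m Bonferroni level and family size (`NULL` = number of loci).
#' @param exclude_bed exclusion-region data.frame (or BED path) for the
#'   gene-set tests.
#' @param ld_max_pairs cap on LD pairs summarized per taxon (`0` disables
#'   the LD stage).
#' @param outlier a [hier_island_config()] for the outlier scan, or `NULL`
#'   to skip it.
#' @param stages character subset of
#'   `c("popstats", "fst", "ld", "geneset", "inversion", "outlier")`.
#' @param out_dir output directory for stage TSVs and the summary JSON, or
#'   `NULL` to keep results in memory only.
#' @param seed master seed; all stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = NULL, vcf = NULL, taxon_table = NULL,
                       genes_bed = NULL, inversions_bed = NULL,
                       immune_list = NULL, codon_usage = NULL,
                       contrasts = NULL, B = 1000L, alpha = 0.05, m = NULL,
                       exclude_bed = NULL, ld_max_pairs = 20000L,
                       outlier = NULL,
                       stages = c("popstats", "fst", "geneset", "inversion"),
                       out_dir = NULL, seed = 1L) {
  known <- c("popstats", "fst", "ld", "geneset", "inversion", "outlier")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(synthetic) && (is.null(vcf) || is.null(taxon_table)))
    stop("either 'synthetic' or input paths (vcf + taxon_table) required")
  structure(list(synthetic = synthetic, vcf = vcf, taxon_table = taxon_table,
                 genes_bed = genes_bed, inversions_bed = inversions_bed,
                 immune_list = immune_list, codon_usage = codon_usage,
                 contrasts = contrasts, B = as.integer(B), alpha = alpha,
                 m = m, exclude_bed = exclude_bed,
                 ld_max_pairs = ld_max_pairs, outlier = outlier,
                 stages = stages, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Independent substream seeds derived from the master seed (kept < 2^31).
derive_seed <- function(seed, k) (seed * 7919L + k * 104729L) %% 2147483647L

#' Run the full divergence analysis
#'
#' Executes the configured stages in order and returns (and optionally
#' writes) per-stage tables plus a summary of headline statistics: the
#' multilocus F_ST per contrast, gene-set bootstrap p per contrast, the
#' SNP-count and inversion-permutation p-values, and outlier flags.
#'
#' @param config a [run_config()].
#' @return list with `summary` (named list of headline numbers), `tables`
#'   (stage data.frames) and `data` (the loaded/generated bundle).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  # -- load or generate ------------------------------------------------
  if (!is.null(config$synthetic)) {
    bundle <- gen_study_mimic(config$synthetic,
                              seed = derive_seed(config$seed, 1L))
  } else {
    gm <- read_vcf(config$vcf, config$taxon_table)
    genes <- NULL; inversions <- NULL; immune_ids <- character(0)
    if (!is.null(config$genes_bed)) {
      ann <- read_annotations(config$genes_bed, config$inversions_bed,
                              config$immune_list)
      genes <- ann$genes; inversions <- ann$inversions
      immune_ids <- genes$gene_id[genes$immune]
      gm <- assign_snps_to_genes(gm, genes)
    }
    bundle <- list(genotypes = gm, genes = genes, inversions = inversions,
                   immune_ids = immune_ids)
  }
  gm <- bundle$genotypes
  exclude_bed <- config$exclude_bed
  if (is.character(exclude_bed)) exclude_bed <- read_bed4(exclude_bed)
  if (is.null(exclude_bed) && !is.null(config$synthetic))
    exclude_bed <- config$synthetic$exclusion_bed
  # -- functional filter ----------------------------------------------
  if (!is.null(config$codon_usage) &&
      all(c("ref_codon", "alt_codon") %in% names(gm$snps))) {
    usage <- read_codon_usage(config$codon_usage)
    kept <- filter_potentially_functional(gm$snps, usage)
    gm <- subset_genotypes(gm, loci = match(kept$id, gm$snps$id))
  }
  contrasts <- config$contrasts
  if (is.null(contrasts)) contrasts <- combn(taxa(gm), 2L, simplify = FALSE)
  tables <- list()
  summary <- list(n_individuals = nrow(gm$calls), n_loci = ncol(gm$calls),
                  n_taxa = length(taxa(gm)))
  # -- per-locus popstats + association --------------------------------
  if ("popstats" %in% config$stages) {
    het <- lapply(setNames(nm = taxa(gm)), function(tx)
      observed_heterozygosity(gm, tx))
    assoc <- association_scan(gm, alpha = config$alpha,
                              m = if (is.null(config$m)) NULL else config$m)
    per_locus <- data.frame(locus = gm$snps$id, chrom = gm$snps$chrom,
                            pos = gm$snps$pos, gene = gm$snps$gene_id,
                            stringsAsFactors = FALSE)
    for (tx in taxa(gm)) {
      inp <- wc_inputs(gm, tx)
      per_locus[[paste0("freq_", tx)]] <- inp$p[, 1]
      per_locus[[paste0("hobs_", tx)]] <- het[[tx]]$per_locus
    }
    per_locus <- cbind(per_locus,
                       assoc[, c("chi2", "df", "p_value", "significant")])
    tables$per_locus <- per_locus
    summary$mean_heterozygosity <-
      lapply(het, function(h) c(mean = h$mean, sd = h$sd,
                                n_invariant = h$n_invariant))
    summary$n_significant_association <- sum(assoc$significant, na.rm = TRUE)
    summary$bonferroni_threshold <- attr(assoc, "threshold")
  }
  # -- pairwise F_ST per contrast --------------------------------------
  if ("fst" %in% config$stages) {
    fst_rows <- list()
    for (ct in contrasts) {
      key <- paste(ct, collapse = "_vs_")
      comp <- wc_fst_all_loci(gm, ct)
      theta_set <- fst_from_components(comp)
      fst_rows[[key]] <- data.frame(contrast = key, locus = comp$locus,
                                    theta = comp$theta,
                                    stringsAsFactors = FALSE)
      summary$set_fst[[key]] <- as.numeric(theta_set)
    }
    tables$fst_per_locus <- do.call(rbind, fst_rows)
  }
  # -- LD summaries ----------------------------------------------------
  if ("ld" %in% config$stages && config$ld_max_pairs > 0 &&
      sum(!is.na(gm$snps$gene_id)) >= 2) {
    set.seed(derive_seed(config$seed, 2L))
    ld_rows <- lapply(setNames(nm = taxa(gm)), function(tx) {
      s <- ld_summary(gm, tx, max_pairs = config$ld_max_pairs)$summary
      cbind(taxon = tx, s)
    })
    tables$ld_summary <- do.call(rbind, ld_rows)
    rownames(tables$ld_summary) <- NULL
    summary$ld_over_0.8 <- setNames(
      lapply(taxa(gm), function(tx) {
        s <- tables$ld_summary
        s$proportion[s$taxon == tx & s$threshold == 0.8]
      }), taxa(gm))
  }
  # -- gene-set tests --------------------------------------------------
  has_genes <- !is.null(bundle$genes) && length(bundle$immune_ids) > 0
  if ("geneset" %in% config$stages && has_genes) {
    gs_rows <- list()
    for (ct in contrasts) {
      key <- paste(ct, collapse = "_vs_")
      res <- geneset_fst_test(gm, ct, bundle$genes, bundle$immune_ids,
                              B = config$B,
                              seed = derive_seed(config$seed, 3L),
                              exclude_bed = exclude_bed)
      gs_rows[[key]] <- data.frame(test = "geneset_fst", contrast = key,
                                   observed = res$observed,
                                   null_mean = res$null_mean,
                                   null_sd = res$null_sd,
                                   null_sem = res$null_sem,
                                   p_value = res$p_value, B = res$B)
      summary$geneset_fst_p[[key]] <- res$p_value
      summary$geneset_fst_observed[[key]] <- res$observed
    }
    snpcount <- geneset_snpcount_test(gm, bundle$genes, bundle$immune_ids,
                                      B = config$B,
                                      seed = derive_seed(config$seed, 4L),
                                      exclude_bed = exclude_bed)
    gs_rows$snpcount <- data.frame(test = "geneset_snpcount", contrast = "all",
                                   observed = snpcount$observed,
                                   null_mean = snpcount$null_mean,
                                   null_sd = snpcount$null_sd,
                                   null_sem = snpcount$null_sem,
                                   p_value = snpcount$p_value, B = snpcount$B)
    summary$snpcount_p <- snpcount$p_value
    tables$geneset_tests <- do.call(rbind, gs_rows)
    rownames(tables$geneset_tests) <- NULL
  }
  # -- inversion permutation -------------------------------------------
  if ("inversion" %in% config$stages && has_genes &&
      !is.null(bundle$inversions)) {
    inv <- inversion_overlap_test(bundle$genes, bundle$immune_ids,
                                  bundle$inversions, B = config$B,
                                  seed = derive_seed(config$seed, 5L))
    tables$inversion_test <- data.frame(observed = inv$observed,
                                        null_mean = inv$null_mean,
                                        null_sd = inv$null_sd,
                                        p_value = inv$p_value, B = inv$B)
    summary$inversion_p <- inv$p_value
    summary$inversion_observed <- inv$observed
    summary$inversion_null_mean <- inv$null_mean
    summary$inversion_null_sd <- inv$null_sd
  }
  # -- outlier scan ----------------------------------------------------
  if ("outlier" %in% config$stages && !is.null(config$outlier)) {
    null <- simulate_hier_island_null(config$outlier,
                                      seed = derive_seed(config$seed, 6L))
    obs <- observed_scan_stats(gm)
    obs <- obs[is.finite(obs$theta), , drop = FALSE]
    scan <- flag_outliers(outlier_pvalues(obs, null), alpha = config$alpha,
                          m = if (is.null(config$m)) nrow(obs) else config$m)
    tables$outlier_scan <- scan
    summary$n_outliers <- sum(scan$flagged, na.rm = TRUE)
  }
  # -- write -----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    write_results(tables, config$out_dir)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, tables = tables, data = bundle)
}
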