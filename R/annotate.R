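# SNP-to-gene interval assignment. Coordinate conventions: SNP positions are
# 1-based (VCF); gene/inversion intervals are 0-based half-open (BED). All
# conversion between the two happens here: a SNP at 1-based position p lies
# in BED interval [start, end) iff start < p <= end.

snps_as_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom,
                         IRanges::IRanges(start = snps$pos, width = 1L))
}

bed_as_granges <- function(bed) {
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(start = bed$start + 1L,
                                          end = bed$end))
}

#' Assign SNPs to genes by genomic position
#'
#' Annotates each SNP with the gene whose interval contains it. A SNP in no
#' gene keeps `gene_id = NA`; a SNP inside several overlapping genes is
#' recorded against all of them in the full assignment table (and carries
#' the first by gene-table order in its `gene_id` column), so per-gene
#' statistics count it once per gene.
#'
#' @param x a `genotype_matrix` or a SNP data.frame (`id`, `chrom`, `pos`).
#' @param genes gene annotation data.frame from [read_annotations()]
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @return the input with `gene_id` filled in; the complete (snp, gene)
#'   pair table is attached to the SNP table as attribute
#'   `"gene_assignments"` and retrievable with [snp_gene_assignments()].
#' @export
assign_snps_to_genes <- function(x, genes) {
  is_gm <- inherits(x, "genotype_matrix")
  snps <- if (is_gm) x$snps else x
  hits <- GenomicRanges::findOverlaps(snps_as_granges(snps),
                                      bed_as_granges(genes))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  assignments <- data.frame(snp_id = snps$id[qh],
                            gene_id = genes$gene_id[sh],
                            stringsAsFactors = FALSE)
  snps$gene_id <- NA_character_
  first <- !duplicated(qh)
  snps$gene_id[qh[first]] <- genes$gene_id[sh[first]]
  attr(snps, "gene_assignments") <- assignments
  if (is_gm) { x$snps <- snps; x } else snps
}

#' Full SNP-to-gene assignment table
#'
#' @param snps a SNP table previously passed through
#'   [assign_snps_to_genes()], or a `genotype_matrix` so annotated.
#' @return data.frame with columns `snp_id`, `gene_id`, one row per
#'   (SNP, containing gene) pair.
#' @export
snp_gene_assignments <- function(snps) {
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  a <- attr(snps, "gene_assignments")
  if (is.null(a)) {
    keep <- !is.na(snps$gene_id)
    a <- data.frame(snp_id = snps$id[keep], gene_id = snps$gene_id[keep],
                    stringsAsFactors = FALSE)
  }
  a
}
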