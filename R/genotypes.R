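# Core genotype container: individuals x biallelic loci, alt-allele dosage
# coded 0/1/2 with NA for missing. Loci are described by a SNP table
# (data.frame) carrying coordinates, alleles, gene assignment and
# functional class.

#' Construct a genotype matrix object
#'
#' The central container for all downstream statistics: a diploid dosage
#' matrix (rows = individuals, columns = biallelic loci, entries = copies of
#' the alternate allele, `NA` = missing call) plus per-individual taxon
#' labels and a per-locus SNP annotation table.
#'
#' @param calls integer matrix of alt-allele dosages in `{0, 1, 2, NA}`;
#'   rows are individuals, columns loci.
#' @param taxon character vector, one taxon label per individual.
#' @param snps data.frame with one row per locus; must contain columns
#'   `id`, `chrom`, `pos` (1-based), `ref`, `alt`; optional `gene_id`
#'   (NA when unassigned) and `functional_class` (one of
#'   [FUNCTIONAL_CLASSES]). Defaults are filled in when absent.
#' @param individuals character vector of individual identifiers; defaults
#'   to rownames of `calls` or `ind1..indN`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `taxon`, `snps`, `individuals`.
#' @export
genotype_matrix <- function(calls, taxon, snps, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) {
    individuals <- rownames(calls)
    if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(calls)))
  }
  taxon <- as.character(taxon)
  if (length(taxon) != nrow(calls))
    stop("'taxon' must have one label per individual (", nrow(calls),
         " rows, ", length(taxon), " labels)")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("snp table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(snps) != ncol(calls))
    stop("snp table has ", nrow(snps), " rows but calls has ", ncol(calls),
         " columns")
  if (!"gene_id" %in% names(snps)) snps$gene_id <- NA_character_
  if (!"functional_class" %in% names(snps)) snps$functional_class <- "UNKNOWN"
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad))
    stop("calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  if (any(snps$pos < 1)) stop("SNP positions are 1-based and must be >= 1")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  rownames(calls) <- individuals
  colnames(calls) <- snps$id
  structure(list(calls = calls, taxon = taxon, snps = snps,
                 individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$taxon)
  cat("genotype_matrix: ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " loci\n", sep = "")
  cat("taxa: ", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                      collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Taxa present in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return character vector of distinct taxon labels, in order of appearance.
#' @export
taxa <- function(x) unique(x$taxon)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param individuals logical/integer/character selector over individuals,
#'   or NULL to keep all.
#' @param loci selector over loci (matched against SNP ids when character),
#'   or NULL to keep all.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  ii <- seq_along(x$individuals)
  jj <- seq_len(ncol(x$calls))
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) match(individuals, x$individuals)
          else ii[individuals]
    if (anyNA(ii)) stop("unknown individual in selection")
  }
  if (!is.null(loci)) {
    jj <- if (is.character(loci)) match(loci, x$snps$id) else jj[loci]
    if (anyNA(jj)) stop("unknown locus in selection")
  }
  genotype_matrix(x$calls[ii, jj, drop = FALSE], x$taxon[ii],
                  x$snps[jj, , drop = FALSE], x$individuals[ii])
}

# Internal: dosage columns for one taxon at given loci, individuals x loci.
taxon_calls <- function(x, taxon, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  keep <- x$taxon == taxon
  if (!any(keep)) stop("no individuals with taxon label '", taxon, "'")
  m <- x$calls[keep, , drop = FALSE]
  if (!is.null(loci)) {
    jj <- if (is.character(loci)) match(loci, x$snps$id) else loci
    m <- m[, jj, drop = FALSE]
  }
  m
}
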