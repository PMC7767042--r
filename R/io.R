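# Readers/writers for the external formats: VCF v4.x (via vcfR), BED4 gene
# and inversion annotations, and the TSV dialect used for taxon tables,
# genotype tables, codon usage and all stage outputs (tab-separated, UTF-8,
# '.' for missing).

#' Read a taxon assignment table
#'
#' Two-column TSV (`individual`, `taxon`), with or without a header line.
#'
#' @param path file path.
#' @return named character vector mapping individual id to taxon label.
#' @export
read_taxon_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("taxon table needs two columns: individual, taxon")
  if (identical(tolower(tab[1, 1]), "individual")) tab <- tab[-1, , drop = FALSE]
  map <- setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  if (anyDuplicated(names(map)))
    stop("duplicated individual id in taxon table: ",
         names(map)[duplicated(names(map))][1])
  map
}

#' Read genotypes from a VCF file
#'
#' Loads biallelic SNP rows from a VCF v4.x file, converting GT fields to
#' alternate-allele dosages. Multi-allelic rows are skipped with a warning
#' (the analysis operates on biallelic SNPs). Missing genotypes (`./.`)
#' become `NA`.
#'
#' @param path VCF file (plain or gzipped).
#' @param taxon_table_path TSV mapping every VCF sample to a taxon label.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, taxon_table_path) {
  taxon_map <- read_taxon_table(taxon_table_path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi))
    warning(sum(multi), " multi-allelic or non-SNP row(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(gt)
  unknown <- setdiff(samples, names(taxon_map))
  if (length(unknown))
    stop("VCF sample(s) absent from taxon table: ",
         paste(unknown, collapse = ", "))
  # dosage = number of non-zero alleles in the GT string; "./." -> NA
  dose_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  calls <- t(apply(gt, 1L, function(row) vapply(row, dose_one, integer(1))))
  if (nrow(fix) == 1L) calls <- matrix(calls, nrow = 1L,
                                       dimnames = list(NULL, samples))
  calls <- t(calls)  # individuals x loci
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  snps <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(calls, taxon = unname(taxon_map[samples]), snps = snps,
                  individuals = samples)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Minimal VCF emitter (GT-only FORMAT, unphased) whose output round-trips
#' through [read_vcf()] with dosages preserved.
#'
#' @param x a `genotype_matrix`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt_str <- matrix("./.", nrow = ncol(x$calls), ncol = nrow(x$calls))
  codes <- c("0/0", "0/1", "1/1")
  tc <- t(x$calls)
  ok <- !is.na(tc)
  gt_str[ok] <- codes[tc[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=divscan",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$individuals), collapse = "\t"))
  body <- paste(x$snps$chrom, x$snps$pos, x$snps$id, x$snps$ref, x$snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a tabular genotype matrix
#'
#' TSV with individuals as rows: first two columns `individual`, `taxon`,
#' remaining columns one locus each with dosage codes 0/1/2 and `.` for
#' missing. Locus metadata beyond the id is not carried by this format;
#' positions default to column order on a pseudo-chromosome.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = ".")
  if (ncol(tab) < 3) stop("genotype table needs individual, taxon, >=1 locus")
  calls <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(calls) <- "integer"
  snps <- data.frame(id = colnames(calls), chrom = "un",
                     pos = seq_len(ncol(calls)), ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, taxon = tab[[2]], snps = snps,
                  individuals = as.character(tab[[1]]))
}

#' Read gene and inversion annotations
#'
#' BED4 files (0-based half-open intervals, columns chrom/start/end/name)
#' for genes and inversions, plus a one-id-per-line immune gene list.
#'
#' @param genes_bed path to gene BED4.
#' @param inversions_bed path to inversion BED4, or `NULL` for none.
#' @param immune_list_path path to immune gene-id list, or `NULL` for none.
#' @return list with `genes` (data.frame: gene_id, chrom, start, end,
#'   immune) and `inversions` (data.frame: name, chrom, start, end).
#' @export
read_annotations <- function(genes_bed, inversions_bed = NULL,
                             immune_list_path = NULL) {
  genes <- read_bed4(genes_bed)
  names(genes)[names(genes) == "name"] <- "gene_id"
  immune_ids <- character(0)
  if (!is.null(immune_list_path)) {
    immune_ids <- readLines(immune_list_path)
    immune_ids <- immune_ids[nzchar(immune_ids)]
    unknown <- setdiff(immune_ids, genes$gene_id)
    if (length(unknown))
      warning(length(unknown), " immune-list id(s) not in gene BED (ignored): ",
              paste(head(unknown, 5), collapse = ", "))
  }
  genes$immune <- genes$gene_id %in% immune_ids
  inversions <- NULL
  if (!is.null(inversions_bed)) inversions <- read_bed4(inversions_bed)
  list(genes = genes, inversions = inversions)
}

read_bed4 <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4) stop("BED file needs >= 4 columns: ", path)
  out <- data.frame(name = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("BED interval with start >= end in ", path)
  out
}

write_bed4 <- function(df, path, name_col = "name") {
  write.table(data.frame(df$chrom, df$start, df$end, df[[name_col]]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a codon usage table
#'
#' TSV with columns `codon` and `frequency`. All 64 codons must be present
#' with strictly positive frequencies; ratios between synonymous codons are
#' what matters, so no normalization is applied.
#'
#' @param path file path.
#' @return named numeric vector of length 64 (names are uppercase codons).
#' @export
read_codon_usage <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("codon", "frequency") %in% names(tab)))
    stop("codon usage table needs columns 'codon' and 'frequency'")
  usage <- setNames(as.numeric(tab$frequency), toupper(tab$codon))
  validate_codon_usage(usage)
  usage
}

validate_codon_usage <- function(usage) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  missing <- setdiff(all_codons, names(usage))
  if (length(missing))
    stop("codon usage table is missing ", length(missing), " codon(s): ",
         paste(head(missing, 5), collapse = ", "))
  if (any(!is.finite(usage)) || any(usage <= 0))
    stop("all codon usage frequencies must be finite and > 0")
  invisible(usage)
}

#' Write analysis stage tables
#'
#' Writes each named data.frame of `tables` to `<out_dir>/<name>.tsv` in the
#' package's TSV dialect (tab-separated, header, no quoting, `NA` as `.`),
#' with deterministic column order and row order as given.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return character vector of paths written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, na = ".")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a stage table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = ".", check.names = FALSE)
}
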