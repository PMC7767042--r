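# Functional SNP classification: a coding SNP is "potentially functional"
# when it changes the encoded amino acid, or when it swaps between
# synonymous codons whose usage frequencies differ at least 2-fold (a proxy
# for altered translation rate / folding).

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a codon: '", codon, "'")
  aa
}

#' Classify a coding SNP by its codon change
#'
#' @param ref_codon,alt_codon three-letter codons differing at exactly one
#'   position.
#' @param codon_position position (1..3) at which they differ.
#' @param usage codon usage table: named numeric vector over all 64 codons
#'   (see [read_codon_usage()]).
#' @param fold_threshold minimum usage-frequency fold change for a
#'   synonymous SNP to count as potentially functional. The threshold is
#'   inclusive: a ratio of exactly `fold_threshold` qualifies.
#' @return one of `"NONSYNONYMOUS"`, `"SYNONYMOUS_FUNCTIONAL"`,
#'   `"SYNONYMOUS_NEUTRAL"`. Stop-gain/loss changes are classified
#'   `NONSYNONYMOUS`.
#' @export
classify_snp <- function(ref_codon, alt_codon, codon_position, usage,
                         fold_threshold = 2) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  if (nchar(ref_codon) != 3L || nchar(alt_codon) != 3L)
    stop("codons must be 3 bases")
  diff_at <- which(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  if (length(diff_at) != 1L)
    stop("codons must differ at exactly one position (differ at ",
         length(diff_at), ")")
  if (!identical(as.integer(codon_position), as.integer(diff_at)))
    stop("codons differ at position ", diff_at, ", not ", codon_position)
  validate_codon_usage(usage)
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_ref != aa_alt || aa_ref == "*" || aa_alt == "*")
    return("NONSYNONYMOUS")
  ratio <- max(usage[[ref_codon]] / usage[[alt_codon]],
               usage[[alt_codon]] / usage[[ref_codon]])
  if (ratio >= fold_threshold) "SYNONYMOUS_FUNCTIONAL" else "SYNONYMOUS_NEUTRAL"
}

#' Classify SNPs carrying codon context and keep the potentially functional
#'
#' SNP rows with codon context (`ref_codon`, `alt_codon`, `codon_position`)
#' are classified with [classify_snp()]; rows without context keep their
#' existing class (`NONCODING`/`UNKNOWN`). The filter then retains
#' `NONSYNONYMOUS` and `SYNONYMOUS_FUNCTIONAL` SNPs, preserving input order.
#'
#' @param snps SNP data.frame; optional columns `ref_codon`, `alt_codon`,
#'   `codon_position` supply codon context.
#' @param usage codon usage table (named numeric over 64 codons).
#' @param fold_threshold see [classify_snp()].
#' @return the subset of rows classified potentially functional, with
#'   `functional_class` filled in.
#' @export
filter_potentially_functional <- function(snps, usage, fold_threshold = 2) {
  snps <- classify_snps(snps, usage, fold_threshold)
  snps[snps$functional_class %in% c("NONSYNONYMOUS", "SYNONYMOUS_FUNCTIONAL"),
       , drop = FALSE]
}

#' @rdname filter_potentially_functional
#' @export
classify_snps <- function(snps, usage, fold_threshold = 2) {
  if (!"functional_class" %in% names(snps)) snps$functional_class <- "UNKNOWN"
  has_ctx <- all(c("ref_codon", "alt_codon", "codon_position") %in% names(snps))
  if (has_ctx) {
    for (i in seq_len(nrow(snps))) {
      if (is.na(snps$ref_codon[i]) || is.na(snps$alt_codon[i])) next
      snps$functional_class[i] <- classify_snp(
        snps$ref_codon[i], snps$alt_codon[i], snps$codon_position[i],
        usage, fold_threshold)
    }
  }
  stopifnot(all(snps$functional_class %in% FUNCTIONAL_CLASSES))
  snps
}
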