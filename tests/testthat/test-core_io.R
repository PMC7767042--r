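# Data model, VCF/BED/TSV round-trips, and SNP-to-gene interval assignment.

make_tiny_vcf <- function(path, taxa_path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("2R", "100", "snpA", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("2R", "200", "snpB", "A", "G", ".", "PASS", ".", "GT",
          "./.", "0/0", "0/1", sep = "\t"),
    paste("2R", "300", "snpC", "A", "G,T", ".", "PASS", ".", "GT",
          "0/0", "1/2", "0/0", sep = "\t"))
  writeLines(lines, path)
  writeLines(c("s1\tcoluzzii", "s2\tbamako", "s3\tbamako"), taxa_path)
  path
}

test_that("VCF GT fields map to dosages, missing and multi-allelic handled", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  taxa_tsv <- withr::local_tempfile(fileext = ".tsv")
  make_tiny_vcf(vcf, taxa_tsv)
  expect_warning(gm <- read_vcf(vcf, taxa_tsv), "multi-allelic")
  expect_equal(ncol(gm$calls), 2L)  # tri-allelic row skipped
  expect_equal(unname(gm$calls[, "snpA"]), c(0L, 1L, 2L))
  expect_true(is.na(gm$calls["s1", "snpB"]))
  expect_equal(gm$taxon, c("coluzzii", "bamako", "bamako"))
})

test_that("VCF sample missing from the taxon table is a hard error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  taxa_tsv <- withr::local_tempfile(fileext = ".tsv")
  make_tiny_vcf(vcf, taxa_tsv)
  writeLines(c("s1\tcoluzzii", "s2\tbamako"), taxa_tsv)
  expect_error(suppressWarnings(read_vcf(vcf, taxa_tsv)),
               "absent from taxon table")
})

test_that("VCF write/read round-trip preserves dosages and annotations", {
  gm <- gen_balding_nichols(c(a = 5L, b = 6L), 20, 0.1, seed = 11)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  taxa_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_vcf(gm, vcf)
  writeLines(paste(gm$individuals, gm$taxon, sep = "\t"), taxa_tsv)
  back <- read_vcf(vcf, taxa_tsv)
  expect_equal(unname(back$calls), unname(gm$calls))
  expect_equal(back$snps$pos, gm$snps$pos)
  expect_equal(back$taxon, gm$taxon)
})

test_that("genotype_matrix enforces its invariants", {
  snps <- data.frame(id = "s", chrom = "1", pos = 1, ref = "A", alt = "T")
  expect_error(genotype_matrix(matrix(3L), "t", snps), "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L), c("t", "u"), snps), "one label")
  expect_error(genotype_matrix(matrix(0L), "t",
                               transform(snps, alt = "A")), "must differ")
  expect_error(genotype_matrix(matrix(0L), "t",
                               transform(snps, pos = 0)), "1-based")
})

test_that("BED annotations read with immune flags; bad intervals rejected", {
  genes_bed <- withr::local_tempfile(fileext = ".bed")
  imm <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2R\t100\t200\tgeneA", "2R\t300\t400\tgeneB"), genes_bed)
  writeLines("geneA", imm)
  ann <- read_annotations(genes_bed, immune_list_path = imm)
  expect_equal(ann$genes$immune, c(TRUE, FALSE))
  # empty immune list -> all FALSE
  writeLines(character(0), imm)
  expect_false(any(read_annotations(genes_bed,
                                    immune_list_path = imm)$genes$immune))
  # unknown immune id -> warning, ignored
  writeLines("geneZ", imm)
  expect_warning(ann2 <- read_annotations(genes_bed, immune_list_path = imm),
                 "not in gene BED")
  expect_false(any(ann2$genes$immune))
  writeLines("2R\t200\t100\tbad", genes_bed)
  expect_error(read_annotations(genes_bed), "start >= end")
})

test_that("SNP-to-gene assignment respects the BED/VCF boundary convention", {
  genes <- data.frame(gene_id = "geneA", chrom = "2R", start = 100L,
                      end = 200L, stringsAsFactors = FALSE)
  snps <- data.frame(id = c("in_first", "out_left", "out_right", "in_last"),
                     chrom = "2R", pos = c(101L, 100L, 250L, 200L),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  out <- assign_snps_to_genes(snps, genes)
  expect_equal(out$gene_id, c("geneA", NA, NA, "geneA"))
})

test_that("overlapping genes each receive the SNP in the assignment table", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "2R",
                      start = c(100L, 140L), end = c(200L, 260L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(id = "s", chrom = "2R", pos = 150L, ref = "A",
                     alt = "T", stringsAsFactors = FALSE)
  out <- assign_snps_to_genes(snps, genes)
  a <- snp_gene_assignments(out)
  expect_setequal(a$gene_id, c("g1", "g2"))
})

test_that("interval assignment agrees with a brute-force scan", {
  set.seed(101)
  for (rep in 1:20) {
    n_genes <- sample(3:8, 1)
    starts <- sort(sample(0:500, n_genes))
    genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)),
                        chrom = sample(c("2R", "3L"), n_genes, TRUE),
                        start = starts,
                        end = starts + sample(20:120, n_genes, TRUE),
                        stringsAsFactors = FALSE)
    snps <- data.frame(id = paste0("s", 1:30),
                       chrom = sample(c("2R", "3L"), 30, TRUE),
                       pos = sample(1:650, 30), ref = "A", alt = "T",
                       stringsAsFactors = FALSE)
    got <- snp_gene_assignments(assign_snps_to_genes(snps, genes))
    want <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      hits <- which(genes$chrom == snps$chrom[i] &
                    genes$start < snps$pos[i] & snps$pos[i] <= genes$end)
      if (!length(hits)) return(NULL)
      data.frame(snp_id = snps$id[i], gene_id = genes$gene_id[hits])
    }))
    key <- function(d) sort(paste(d$snp_id, d$gene_id))
    expect_equal(key(got), if (is.null(want)) character(0) else key(want))
  }
})

test_that("stage tables round-trip and rewrite deterministically", {
  out_dir <- withr::local_tempdir()
  tabs <- list(stats = data.frame(locus = c("a", "b"),
                                  theta = c(0.1, NA),
                                  p = c(0.01, 0.5)),
               empty = data.frame(locus = character(0), p = numeric(0)))
  paths <- write_results(tabs, out_dir)
  back <- read_result_table(file.path(out_dir, "stats.tsv"))
  expect_equal(back$theta, c(0.1, NA))
  expect_equal(nrow(read_result_table(file.path(out_dir, "empty.tsv"))), 0L)
  md5_1 <- tools::md5sum(file.path(out_dir, "stats.tsv"))
  write_results(tabs, out_dir)
  expect_equal(tools::md5sum(file.path(out_dir, "stats.tsv")), md5_1)
})
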