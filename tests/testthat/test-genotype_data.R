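test_that("genotype strings decode to alt-allele counts and bad alleles error", {
  paths <- write_toy_tables()
  expect_message(ds <- load_cohort(paths$geno, paths$pheno),
                 "matched 3 subjects; dropped 1")
  expect_s3_class(ds, "cohort_dataset")
  expect_identical(unname(ds$geno[, "rs1801725"]), c(0L, 1L, 2L))
  expect_identical(unname(ds$geno[, "rs1042636"]), c(0L, 1L, NA))

  # unordered genotype: TG is the same call as GT
  gt <- read.delim(paths$geno, colClasses = "character")
  gt$rs1801725[2] <- "TG"
  write.table(gt, paths$geno, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- load_cohort(paths$geno, paths$pheno, quiet = TRUE)
  expect_identical(ds2$geno[, "rs1801725"], ds$geno[, "rs1801725"])

  # allele not in {ref, alt} names subject, SNP and value
  gt$rs1801725[1] <- "GA"
  write.table(gt, paths$geno, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(paths$geno, paths$pheno, quiet = TRUE),
               "invalid genotype 'GA' for subject A1 at rs1801725")
})

test_that("duplicate subject IDs are rejected", {
  paths <- write_toy_tables()
  ph <- read.delim(paths$pheno)
  ph$subject_id[2] <- "A1"
  write.table(ph, paths$pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(paths$geno, paths$pheno, quiet = TRUE),
               "duplicate subject ID")
})

test_that("TSV round-trip preserves genotype codes and phenotypes", {
  ds <- ksd_cohort(seed = 7)
  dir <- withr::local_tempdir()
  write_cohort(ds, file.path(dir, "g.tsv"), file.path(dir, "p.tsv"))
  ds2 <- load_cohort(file.path(dir, "g.tsv"), file.path(dir, "p.tsv"),
                     quiet = TRUE)
  expect_identical(ds2$geno[rownames(ds$geno), colnames(ds$geno)], ds$geno)
  expect_equal(ds2$pheno$serum_calcium, ds$pheno$serum_calcium,
               tolerance = 1e-9)
  expect_identical(ds2$pheno$status, ds$pheno$status)
})

test_that("reference count tables match the study marginals", {
  counts <- ksd_counts()
  expect_length(counts, 8L)
  for (cc in counts) {
    expect_identical(cc$case$n_total, 200L)
    expect_identical(cc$control$n_total, 200L)
  }
  expect_identical(
    unname(unlist(counts[["rs731236"]]$case[c("n_hom_ref", "n_het",
                                              "n_hom_alt")])),
    c(60L, 82L, 58L))
  expect_identical(counts[["rs1801726"]]$case$n_hom_alt, 0L)
  expect_identical(counts[["rs1801726"]]$control$n_hom_alt, 0L)
})

test_that("counts_from_dataset recovers per-group counts and drops missing", {
  ds <- ksd_cohort(seed = 2)
  cc <- counts_from_dataset(ds, "rs1042636")
  expect_identical(c(cc$case$n_hom_ref, cc$case$n_het, cc$case$n_hom_alt),
                   c(86L, 99L, 15L))
  expect_identical(c(cc$control$n_hom_ref, cc$control$n_het,
                     cc$control$n_hom_alt),
                   c(130L, 69L, 1L))
  cc2 <- counts_from_dataset(ds, "rs219780")
  expect_identical(c(cc2$case$n_hom_ref, cc2$case$n_het, cc2$case$n_hom_alt),
                   c(139L, 58L, 3L))
  expect_error(counts_from_dataset(ds, "rs999"), "unknown snp_id")

  # missing genotypes are excluded from the counts
  ds$geno[ds$pheno$status == "case", "rs1042636"][1:10] <- NA
  cc3 <- counts_from_dataset(ds, "rs1042636")
  expect_identical(cc3$case$n_total, 190L)
  expect_identical(cc3$control$n_total, 200L)
})

test_that("allele counts and frequencies follow from genotype counts", {
  gc <- genotype_counts("rs1801725", "case", 116, 82, 2)
  expect_identical(allele_counts(gc), c(n_ref = 314L, n_alt = 86L))
  gc2 <- genotype_counts("rs219778", "control", 178, 21, 1)
  expect_identical(allele_counts(gc2), c(n_ref = 377L, n_alt = 23L))
  expect_identical(allele_counts(genotype_counts("x", "case", 10, 0, 0)),
                   c(n_ref = 20L, n_alt = 0L))

  expect_equal(allele_frequency(genotype_counts("rs1042636", "case",
                                                86, 99, 15)), 0.3225)
  expect_equal(allele_frequency(genotype_counts("rs1801725", "control",
                                                162, 37, 1)), 0.0975)
  expect_equal(allele_frequency(genotype_counts("x", "case", 10, 0, 0)), 0)
  expect_error(allele_frequency(genotype_counts("x", "case", 0, 0, 0)),
               "no genotyped subjects")
})

test_that("allele totals are conserved through counting", {
  ds <- ksd_cohort(seed = 5)
  for (id in colnames(ds$geno)) {
    cc <- counts_from_dataset(ds, id)
    for (grp in c("case", "control")) {
      ac <- allele_counts(cc[[grp]])
      expect_identical(unname(sum(ac)), 2L * cc[[grp]]$n_total)
    }
  }
})

test_that("VCF import codes diploid GT fields as alt-allele counts", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", sep = "\t"),
    paste("3", "100", "rs1801725", "G", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("3", "200", "rs1042636", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t")), vcf)
  g <- read_vcf_genotypes(vcf)
  expect_identical(unname(g[, "rs1801725"]), c(0L, 1L, 2L))
  expect_identical(unname(g[, "rs1042636"]), c(1L, NA_integer_, 0L))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", sep = "\t"),
    paste("3", "100", "rsX", "G", "T,C", ".", "PASS", ".", "GT", "0/1",
          sep = "\t")), vcf)
  expect_error(read_vcf_genotypes(vcf), "multi-allelic")
})
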