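#' Assemble a cohort dataset
#'
#' A `cohort_dataset` bundles the subjects-by-SNPs genotype matrix (coded as
#' alt-allele counts 0/1/2, `NA` = missing) with the phenotype table (case or
#' control status, covariates, quantitative traits) and the SNP definitions.
#'
#' @param snps named list of [snp_def()] objects; names are rsIDs.
#' @param pheno data frame with columns `subject_id` (unique strings),
#'   `status` (`"case"`/`"control"`), and any covariate/trait columns (e.g.
#'   `age`, `sex`, `bmi`, `serum_calcium`).
#' @param geno integer matrix of alt-allele counts; rows are subjects in the
#'   order of `pheno`, columns are SNP ids that must all appear in `snps`.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(snps, pheno, geno) {
  stopifnot(is.list(snps), is.data.frame(pheno), is.matrix(geno))
  if (!all(vapply(snps, inherits, TRUE, "snp_def")))
    stop("snps must be a list of snp_def objects")
  if (is.null(names(snps)) || any(names(snps) == ""))
    names(snps) <- vapply(snps, `[[`, "", "snp_id")
  if (!all(c("subject_id", "status") %in% names(pheno)))
    stop("pheno must contain subject_id and status columns")
  if (anyDuplicated(pheno$subject_id))
    stop("duplicate subject ID: ",
         pheno$subject_id[duplicated(pheno$subject_id)][1])
  if (!all(pheno$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (nrow(geno) != nrow(pheno))
    stop("geno and pheno describe different numbers of subjects")
  if (!all(colnames(geno) %in% names(snps)))
    stop("genotype columns without a SNP definition: ",
         paste(setdiff(colnames(geno), names(snps)), collapse = ", "))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  rownames(geno) <- pheno$subject_id
  structure(list(snps = snps[colnames(geno)], pheno = pheno, geno = geno),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%d case / %d control), %d SNPs\n",
              nrow(x$pheno), sum(x$pheno$status == "case"),
              sum(x$pheno$status == "control"), ncol(x$geno)))
  cat("  SNPs:", paste(colnames(x$geno), collapse = ", "), "\n")
  traits <- setdiff(names(x$pheno), c("subject_id", "status"))
  if (length(traits)) cat("  pheno:", paste(traits, collapse = ", "), "\n")
  invisible(x)
}

decode_genotype <- function(gt, snp) {
  # two-character unordered genotype string -> alt-allele count
  gt <- toupper(trimws(gt))
  if (is.na(gt) || gt %in% c("", "--", "..", "NN", "NA")) return(NA_integer_)
  if (nchar(gt) != 2L) return(-1L)
  al <- strsplit(gt, "")[[1]]
  if (!all(al %in% c(snp$ref_allele, snp$alt_allele))) return(-1L)
  sum(al == snp$alt_allele)
}

encode_genotype <- function(code, snp) {
  if (is.na(code)) return("--")
  paste0(strrep(snp$ref_allele, 2L - code), strrep(snp$alt_allele, code))
}

#' Load a cohort from genotype and phenotype TSV files
#'
#' The genotype file has one header row, subjects as rows, a `subject_id`
#' column, and one column per SNP holding unordered two-character genotype
#' strings (`"GT"` is the same genotype as `"TG"`; `"--"` or empty = missing).
#' The phenotype file has `subject_id`, `status` and any further columns.
#' Only subjects present in both files are kept; the join is reported.
#'
#' @param genotype_table,phenotype_table paths to the two TSV files.
#' @param snps named list of [snp_def()] giving the allele coding of every
#'   genotype column; defaults to the bundled panel [ksd_snps()].
#' @param quiet suppress the join report message.
#' @return A [cohort_dataset()].
#' @export
load_cohort <- function(genotype_table, phenotype_table, snps = ksd_snps(),
                        quiet = FALSE) {
  stopifnot(file.exists(genotype_table), file.exists(phenotype_table))
  gt <- read.delim(genotype_table, colClasses = "character",
                   check.names = FALSE)
  ph <- read.delim(phenotype_table, check.names = FALSE)
  for (df_name in c("genotype", "phenotype")) {
    df <- if (df_name == "genotype") gt else ph
    if (!"subject_id" %in% names(df))
      stop(df_name, " table lacks a subject_id column")
    if (anyDuplicated(df$subject_id))
      stop("duplicate subject ID in ", df_name, " table: ",
           df$subject_id[duplicated(df$subject_id)][1])
  }
  snp_cols <- setdiff(names(gt), "subject_id")
  missing_defs <- setdiff(snp_cols, names(snps))
  if (length(missing_defs))
    stop("no SNP definition for genotype column(s): ",
         paste(missing_defs, collapse = ", "))

  ids <- intersect(ph$subject_id, gt$subject_id)
  if (!length(ids)) stop("no subject IDs shared between the two tables")
  n_drop <- length(union(ph$subject_id, gt$subject_id)) - length(ids)
  if (n_drop > 0 && !quiet)
    message("load_cohort: matched ", length(ids), " subjects; dropped ",
            n_drop, " present in only one table")
  ph <- ph[match(ids, ph$subject_id), , drop = FALSE]
  gt <- gt[match(ids, gt$subject_id), , drop = FALSE]

  geno <- matrix(NA_integer_, nrow = length(ids), ncol = length(snp_cols),
                 dimnames = list(ids, snp_cols))
  for (s in snp_cols) {
    snp <- snps[[s]]
    codes <- vapply(gt[[s]], decode_genotype, integer(1), snp = snp)
    if (any(codes == -1L, na.rm = TRUE)) {
      i <- which(codes == -1L)[1]
      stop(sprintf(
        "invalid genotype '%s' for subject %s at %s (alleles are %s/%s)",
        gt[[s]][i], ids[i], s, snp$ref_allele, snp$alt_allele))
    }
    geno[, s] <- codes
  }
  cohort_dataset(snps[snp_cols], as.data.frame(ph), geno)
}

#' Write a cohort to the genotype/phenotype TSV dialect
#'
#' Inverse of [load_cohort()]: genotype codes are re-encoded as two-character
#' allele strings, missing as `"--"`.
#'
#' @param ds a [cohort_dataset()].
#' @param genotype_table,phenotype_table output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(ds, genotype_table, phenotype_table) {
  stopifnot(inherits(ds, "cohort_dataset"))
  gt <- data.frame(subject_id = ds$pheno$subject_id, check.names = FALSE)
  for (s in colnames(ds$geno))
    gt[[s]] <- vapply(ds$geno[, s], encode_genotype, "", snp = ds$snps[[s]])
  write.table(gt, genotype_table, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$pheno, phenotype_table, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genotype_table, phenotype_table))
}

#' Per-group genotype counts for one SNP
#'
#' Missing genotypes are excluded, so counts sum to the number of non-missing
#' subjects in each group.
#'
#' @param ds a [cohort_dataset()].
#' @param snp_id rsID present in `ds`.
#' @return List with components `case` and `control`, both
#'   [genotype_counts()].
#' @export
counts_from_dataset <- function(ds, snp_id) {
  stopifnot(inherits(ds, "cohort_dataset"))
  if (!snp_id %in% colnames(ds$geno))
    stop("unknown snp_id: ", snp_id)
  out <- lapply(c(case = "case", control = "control"), function(grp) {
    g <- ds$geno[ds$pheno$status == grp, snp_id]
    genotype_counts(snp_id, grp,
                    sum(g == 0L, na.rm = TRUE),
                    sum(g == 1L, na.rm = TRUE),
                    sum(g == 2L, na.rm = TRUE))
  })
  out
}

#' Import genotypes from a VCF file
#'
#' Reads diploid GT fields from a VCF 4.x file via the vcfR package and codes
#' them as alt-allele counts (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2, `./.` ->
#' missing). Multi-allelic records are rejected: the panel SNPs are biallelic.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF file.
#' @return Integer matrix, samples as rows, variant IDs as columns.
#' @export
read_vcf_genotypes <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF import")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF record(s): ",
         paste(vcfR::getID(v)[grepl(",", alt)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  x <- gsub("\\|", "/", as.vector(gt))
  codes <- ifelse(x == "0/0", 0L,
                  ifelse(x %in% c("0/1", "1/0"), 1L,
                         ifelse(x == "1/1", 2L, NA_integer_)))
  t(matrix(codes, nrow = nrow(gt), dimnames = dimnames(gt)))
}
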