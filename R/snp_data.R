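#' Define a biallelic SNP
#'
#' A `snp_def` records the identity and allele coding of one biallelic SNP:
#' rsID, gene label, reference and alternate allele, which of the two is the
#' risk allele, and a free-text annotation (e.g. the amino-acid change).
#'
#' @param snp_id rsID string.
#' @param gene gene symbol.
#' @param ref_allele,alt_allele single-character bases; must differ.
#' @param risk_allele `"ref"` or `"alt"`: which allele is treated as the risk
#'   allele in downstream scoring.
#' @param annotation free label, e.g. `"Ala986Ser"`.
#' @return An object of class `snp_def` (a named list).
#' @examples
#' snp_def("rs1801725", "CaSR", "G", "T", annotation = "Ala986Ser")
#' @export
snp_def <- function(snp_id, gene = NA_character_, ref_allele, alt_allele,
                    risk_allele = c("alt", "ref"), annotation = NA_character_) {
  risk_allele <- match.arg(risk_allele)
  stopifnot(is.character(snp_id), length(snp_id) == 1L, nzchar(snp_id))
  if (!is.character(ref_allele) || nchar(ref_allele) != 1L ||
      !is.character(alt_allele) || nchar(alt_allele) != 1L)
    stop("ref_allele and alt_allele must be single-character bases")
  if (identical(ref_allele, alt_allele))
    stop("ref_allele and alt_allele must differ for SNP ", snp_id)
  structure(
    list(snp_id = snp_id, gene = gene, ref_allele = ref_allele,
         alt_allele = alt_allele, risk_allele = risk_allele,
         annotation = annotation),
    class = "snp_def"
  )
}

#' @export
print.snp_def <- function(x, ...) {
  cat(sprintf("<snp_def> %s (%s) %s>%s risk=%s %s\n", x$snp_id,
              x$gene, x$ref_allele, x$alt_allele,
              if (x$risk_allele == "alt") x$alt_allele else x$ref_allele,
              ifelse(is.na(x$annotation), "", x$annotation)))
  invisible(x)
}

#' Genotype counts of one SNP in one group
#'
#' The unit of all count-based tests: numbers of homozygous-reference,
#' heterozygous and homozygous-alternate subjects for a single SNP in a
#' single group (cases or controls).
#'
#' @param snp_id rsID string.
#' @param group `"case"` or `"control"`.
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer counts.
#' @return An object of class `genotype_counts`.
#' @examples
#' genotype_counts("rs1042636", "case", 86, 99, 15)
#' @export
genotype_counts <- function(snp_id, group = c("case", "control"),
                            n_hom_ref, n_het, n_hom_alt) {
  group <- match.arg(group)
  n <- c(n_hom_ref, n_het, n_hom_alt)
  if (length(n) != 3L || any(is.na(n)) || any(n < 0) || any(n != round(n)))
    stop("counts must be non-negative integers")
  structure(
    list(snp_id = snp_id, group = group,
         n_hom_ref = as.integer(n_hom_ref), n_het = as.integer(n_het),
         n_hom_alt = as.integer(n_hom_alt),
         n_total = as.integer(sum(n))),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s [%s] homRef/het/homAlt = %d/%d/%d (n=%d)\n",
              x$snp_id, x$group, x$n_hom_ref, x$n_het, x$n_hom_alt, x$n_total))
  invisible(x)
}

#' Allele counts from genotype counts
#'
#' @param gc a [genotype_counts()] object.
#' @return Named integer vector `c(n_ref, n_alt)`; the two entries sum to
#'   twice the number of genotyped subjects.
#' @examples
#' allele_counts(genotype_counts("rs1801725", "case", 116, 82, 2))
#' @export
allele_counts <- function(gc) {
  stopifnot(inherits(gc, "genotype_counts"))
  c(n_ref = 2L * gc$n_hom_ref + gc$n_het,
    n_alt = gc$n_het + 2L * gc$n_hom_alt)
}

#' Alternate-allele frequency from genotype counts
#'
#' @inheritParams allele_counts
#' @return Alt-allele frequency in `[0, 1]`.
#' @export
allele_frequency <- function(gc) {
  stopifnot(inherits(gc, "genotype_counts"))
  if (gc$n_total == 0L)
    stop("allele frequency undefined: no genotyped subjects for ", gc$snp_id)
  unname(allele_counts(gc)["n_alt"] / (2 * gc$n_total))
}

#' Reference SNP definitions for the kidney-stone candidate-gene panel
#'
#' The eight biallelic SNPs of the CaSR, VDR and CLDN14 candidate-gene panel,
#' with allele coding and risk-allele designation. The alternate (variant)
#' allele is the risk allele at every SNP; the designation is recorded
#' explicitly rather than inferred from frequency.
#'
#' @return A named list of [snp_def()] objects, keyed by rsID.
#' @seealso [ksd_counts()] for the matching genotype count tables.
#' @export
ksd_snps <- function() {
  defs <- list(
    snp_def("rs1801725", "CaSR",   "G", "T", "alt", "Ala986Ser"),
    snp_def("rs1042636", "CaSR",   "A", "G", "alt", "Arg990Gly"),
    snp_def("rs1801726", "CaSR",   "C", "G", "alt", "Glu1011Gln"),
    snp_def("rs2228570", "VDR",    "C", "T", "alt", "Met1Thr (FokI)"),
    snp_def("rs731236",  "VDR",    "C", "T", "alt", "TaqI, intronic"),
    snp_def("rs219777",  "CLDN14", "C", "T", "alt", "intronic"),
    snp_def("rs219778",  "CLDN14", "T", "C", "alt", "intronic"),
    snp_def("rs219780",  "CLDN14", "G", "A", "alt", "Thr229Thr")
  )
  setNames(defs, vapply(defs, `[[`, "", "snp_id"))
}

#' Reference genotype counts for the kidney-stone candidate-gene panel
#'
#' Per-SNP genotype counts (homRef/het/homAlt) in 200 kidney-stone cases and
#' 200 matched controls for the eight candidate SNPs, as reported for an
#' eastern-India calcium kidney-stone cohort. These printed counts are the
#' ground truth for all count-based statistics in this package; every group
#' sums to 200.
#'
#' @return A named list keyed by rsID; each element is a list with components
#'   `case` and `control`, both [genotype_counts()] objects.
#' @examples
#' ksd_counts()[["rs731236"]]$case
#' @export
ksd_counts <- function() {
  tab <- list(
    rs1801725 = list(case = c(116, 82, 2),  control = c(162, 37, 1)),
    rs1042636 = list(case = c(86, 99, 15),  control = c(130, 69, 1)),
    rs1801726 = list(case = c(189, 11, 0),  control = c(190, 10, 0)),
    rs2228570 = list(case = c(78, 115, 7),  control = c(98, 90, 12)),
    rs731236  = list(case = c(60, 82, 58),  control = c(77, 58, 65)),
    rs219777  = list(case = c(159, 38, 3),  control = c(174, 25, 1)),
    rs219778  = list(case = c(141, 56, 3),  control = c(178, 21, 1)),
    rs219780  = list(case = c(139, 58, 3),  control = c(169, 30, 1))
  )
  lapply(setNames(names(tab), names(tab)), function(id) {
    list(case = genotype_counts(id, "case", tab[[id]]$case[1],
                                tab[[id]]$case[2], tab[[id]]$case[3]),
         control = genotype_counts(id, "control", tab[[id]]$control[1],
                                   tab[[id]]$control[2], tab[[id]]$control[3]))
  })
}
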