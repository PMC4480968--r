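#' Log-odds-ratio weights for the allele dosage score
#'
#' @param snp_ids ordered character vector of k rsIDs.
#' @param or per-SNP odds ratios of the risk allele; must all exceed 1 so
#'   that the log weights are positive.
#' @param base logarithm base for the weights. The dosage score depends on
#'   weights only through their ratios, so the base is immaterial; natural
#'   log is the default.
#' @param source free label recording which OR set the weights came from.
#' @return Object of class `dosage_weights` with components `snp_ids`, `W`,
#'   `source`.
#' @export
dosage_weights <- function(snp_ids, or, base = exp(1),
                           source = "user") {
  stopifnot(length(snp_ids) == length(or), length(or) >= 1)
  if (any(or <= 1))
    stop("all odds ratios must exceed 1 (risk-allele orientation)")
  structure(list(snp_ids = snp_ids, W = setNames(log(or, base = base),
                                                 snp_ids),
                 source = source),
            class = "dosage_weights")
}

#' Default dosage weights: allelic ORs of the four associated SNPs
#'
#' Log odds-ratio weights built from the crude allelic ORs of the four SNPs
#' significantly associated with kidney-stone disease in the bundled
#' reference counts (rs1801725, rs1042636, rs219778, rs219780), computed
#' from [ksd_counts()] at run time.
#'
#' @return A [dosage_weights()] object for the four SNPs.
#' @export
ksd_dosage_weights <- function() {
  ids <- c("rs1801725", "rs1042636", "rs219778", "rs219780")
  counts <- ksd_counts()[ids]
  ors <- vapply(counts, function(cc) {
    ca <- allele_counts(cc$case); co <- allele_counts(cc$control)
    odds_ratio_woolf(ca[["n_alt"]], ca[["n_ref"]],
                     co[["n_alt"]], co[["n_ref"]])$or
  }, numeric(1))
  dosage_weights(ids, ors, source = "reference allelic ORs")
}

#' Weighted allele dosage score and "effective" risk-allele count
#'
#' The dosage score of a subject is the weighted mean of the per-locus
#' risk-allele proportion, `score = sum(W_i * R_i / 2) / sum(W_i)`, where
#' `R_i` in `{0, 1, 2}` counts risk alleles at locus i and `W_i` is the log
#' OR weight. The "effective" number of risk alleles rescales the score to
#' the range of a plain allele count: `effective = score * 2k`,
#' algebraically `k * sum(W_i R_i) / sum(W_i)`. With equal weights it
#' reduces to the unweighted risk-allele count; a subject homozygous for the
#' risk allele at all k loci scores `2k`.
#'
#' @param R integer vector of risk-allele counts, one per weighted SNP, each
#'   in `{0, 1, 2}`.
#' @param weights a [dosage_weights()] object; `length(R)` must equal `k`.
#' @return List with `score` (in `[0, 1]`) and `effective_alleles` (in
#'   `[0, 2k]`).
#' @examples
#' w <- ksd_dosage_weights()
#' dosage_score(c(2, 0, 0, 0), w)
#' @export
dosage_score <- function(R, weights) {
  stopifnot(inherits(weights, "dosage_weights"))
  k <- length(weights$W)
  if (length(R) != k) stop("R must have one entry per weighted SNP")
  if (any(is.na(R)) || !all(R %in% 0:2))
    stop("risk-allele counts must be 0, 1 or 2")
  score <- sum(weights$W * (R / 2)) / sum(weights$W)
  list(score = score, effective_alleles = score * 2 * k)
}

# per-subject risk-allele count matrix for a SNP set (NA where missing);
# risk allele may be ref or alt per the snp_def
risk_allele_matrix <- function(ds, snp_ids) {
  missing_snps <- setdiff(snp_ids, colnames(ds$geno))
  if (length(missing_snps))
    stop("unknown snp_id(s): ", paste(missing_snps, collapse = ", "))
  R <- ds$geno[, snp_ids, drop = FALSE]
  for (s in snp_ids)
    if (ds$snps[[s]]$risk_allele == "ref") R[, s] <- 2L - R[, s]
  R
}

#' Combined risk-allele carrier analysis
#'
#' Compares disease odds between two disjoint strata defined by how many of
#' a set of SNPs a subject carries at least one risk allele of ("carried
#' loci"). Subjects missing a genotype at any SNP in the set are excluded,
#' so strata are defined on complete multi-locus genotypes only.
#'
#' @param ds a [cohort_dataset()].
#' @param snp_ids the SNP set (risk alleles per their [snp_def()]).
#' @param stratum_a,stratum_b stratum definitions: `"all"` (risk allele
#'   carried at every SNP in the set), `"none"` (at no SNP), `"single"`
#'   (exactly one SNP), or an integer vector of carried-locus counts. The
#'   two strata must be disjoint; `stratum_a` is the exposed stratum.
#' @return One-row data frame as from [model_contrasts()]: Woolf OR of
#'   case status for stratum_a vs stratum_b, 95% CI, p (chi-square, or
#'   Fisher when any expected cell < 5), plus `n_excluded_missing`.
#' @examples
#' ds <- ksd_cohort(seed = 1)
#' combined_carrier_or(ds, c("rs1801725", "rs1042636"), "all", "none")
#' @export
combined_carrier_or <- function(ds, snp_ids, stratum_a = "all",
                                stratum_b = "none") {
  stopifnot(inherits(ds, "cohort_dataset"), length(snp_ids) >= 1)
  k <- length(snp_ids)
  resolve <- function(s) {
    if (is.character(s))
      switch(s, all = k, none = 0L, single = 1L,
             stop("unknown stratum spec: ", s))
    else as.integer(s)
  }
  ca <- resolve(stratum_a); cb <- resolve(stratum_b)
  if (length(intersect(ca, cb)))
    stop("strata are not disjoint (both include carried-locus count ",
         paste(intersect(ca, cb), collapse = ", "), ")")
  R <- risk_allele_matrix(ds, snp_ids)
  complete <- rowSums(is.na(R)) == 0
  carried <- rowSums(R[complete, , drop = FALSE] >= 1L)
  status <- ds$pheno$status[complete]
  in_a <- carried %in% ca; in_b <- carried %in% cb
  for (nm in c("a", "b")) {
    sel <- if (nm == "a") in_a else in_b
    if (!any(sel))
      stop("stratum_", nm, " is empty (carried-locus count ",
           paste(if (nm == "a") ca else cb, collapse = "/"), ")")
  }
  lab <- function(cnt) if (length(cnt) == 1 && cnt == k) "all loci"
    else if (length(cnt) == 1 && cnt == 0) "no locus"
    else paste0(paste(cnt, collapse = "/"), " loci")
  res <- contrast_2x2(
    paste(snp_ids, collapse = "+"), "combined_carrier",
    paste("risk allele at", lab(ca), "vs", lab(cb)),
    sum(in_a & status == "case"), sum(in_b & status == "case"),
    sum(in_a & status == "control"), sum(in_b & status == "control"))
  res$n_excluded_missing <- sum(!complete)
  res
}

#' Category-wise risk by "effective" risk-allele count
#'
#' Computes every subject's effective risk-allele count under the given
#' weights, bins subjects into categories, and estimates the odds ratio of
#' disease for each category against the lowest (reference) category.
#'
#' Default boundaries `c(2, 3, 4)` give the categories `<=2` (reference,
#' "two or fewer"), `(2,3]`, `(3,4]` and `>4`; intervals are closed on the
#' right. Subjects missing a genotype at any weighted SNP are excluded.
#'
#' @param ds a [cohort_dataset()].
#' @param weights a [dosage_weights()] object; defaults to
#'   [ksd_dosage_weights()].
#' @param boundaries increasing numeric category cut points.
#' @return List of class `dosage_result`: `subjects` (data frame with
#'   per-subject score, effective alleles, category), `categories` (data
#'   frame with per-category n, case/control split, fraction of the cohort,
#'   OR vs reference with CI and p), `n_excluded_missing`.
#' @export
dosage_category_analysis <- function(ds, weights = ksd_dosage_weights(),
                                     boundaries = c(2, 3, 4)) {
  stopifnot(inherits(ds, "cohort_dataset"), inherits(weights, "dosage_weights"))
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  k <- length(weights$W)
  R <- risk_allele_matrix(ds, weights$snp_ids)
  complete <- rowSums(is.na(R)) == 0
  Rc <- R[complete, , drop = FALSE]
  W <- weights$W
  score <- as.numeric(Rc %*% (W / 2)) / sum(W)
  effective <- score * 2 * k

  breaks <- c(-Inf, boundaries, Inf)
  lab <- c(paste0("<=", boundaries[1]),
           paste0("(", boundaries[-length(boundaries)], ",",
                  boundaries[-1], "]"),
           paste0(">", boundaries[length(boundaries)]))
  category <- cut(effective, breaks = breaks, labels = lab, right = TRUE)
  status <- ds$pheno$status[complete]

  subjects <- data.frame(
    subject_id = ds$pheno$subject_id[complete], status = status,
    score = score, effective_alleles = effective, category = category,
    stringsAsFactors = FALSE)

  occupied <- levels(category)[tabulate(category, nbins = length(lab)) > 0]
  if (length(occupied) <= 1) {
    message("dosage_category_analysis: all subjects fall in one category (",
            occupied, "); no odds ratios to compute")
    cats <- data.frame(category = occupied,
                       n = length(effective),
                       n_case = sum(status == "case"),
                       n_control = sum(status == "control"),
                       fraction = 1,
                       or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(subjects = subjects, categories = cats,
                          weights = weights,
                          n_excluded_missing = sum(!complete)),
                     class = "dosage_result"))
  }
  ref <- occupied[1]
  if (ref != lab[1])
    stop("reference category ", lab[1], " is empty")
  rows <- lapply(occupied, function(cl) {
    n_case <- sum(status == "case" & category == cl)
    n_ctrl <- sum(status == "control" & category == cl)
    row <- data.frame(category = cl, n = n_case + n_ctrl,
                      n_case = n_case, n_control = n_ctrl,
                      fraction = (n_case + n_ctrl) / length(effective),
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    if (cl != ref) {
      cc <- contrast_2x2(
        "dosage", "dosage_category", paste(cl, "vs", ref),
        n_case, sum(status == "case" & category == ref),
        n_ctrl, sum(status == "control" & category == ref))
      row$or <- cc$or; row$ci_low <- cc$ci_low; row$ci_high <- cc$ci_high
      row$p <- cc$p_raw
    }
    row
  })
  structure(list(subjects = subjects, categories = do.call(rbind, rows),
                 weights = weights, n_excluded_missing = sum(!complete)),
            class = "dosage_result")
}

#' @export
print.dosage_result <- function(x, ...) {
  cat(sprintf("<dosage_result> %d subjects scored (%d excluded for missing genotypes)\n",
              nrow(x$subjects), x$n_excluded_missing))
  print(transform(x$categories, fraction = round(fraction, 3),
                  or = round(or, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Bar plot of category-wise odds ratios
#'
#' @param x a `dosage_result` from [dosage_category_analysis()].
#' @param main plot title.
#' @return Invisibly, `x`.
#' @export
plot_dosage_or <- function(x, main = "Risk by effective risk-allele count") {
  stopifnot(inherits(x, "dosage_result"))
  cats <- x$categories
  ors <- ifelse(is.na(cats$or), 1, cats$or)
  bp <- graphics::barplot(ors, names.arg = paste0(cats$category, "\n(n=",
                                                  cats$n, ")"),
                          ylab = "Odds ratio vs reference", main = main,
                          ylim = c(0, max(c(ors, cats$ci_high), na.rm = TRUE) * 1.05))
  ok <- !is.na(cats$ci_low)
  graphics::arrows(bp[ok], cats$ci_low[ok], bp[ok], cats$ci_high[ok],
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}
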