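#' Two-sample t-test from summary statistics
#'
#' Student's pooled-variance t-test (default) or Welch's unequal-variance
#' variant, computed from group means, standard deviations and sizes. The
#' statistic is positive when the group-2 mean exceeds the group-1 mean.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' # serum calcium, 4-risk-allele carriers (n = 9) vs others (n = 282)
#' t_test_summary(9.46, 0.28, 282, 9.73, 0.21, 9)
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (variant == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) return(list(t = 0, df = df, p = 1))
  t <- (mean2 - mean1) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments;
# handles ties via midranks. Feasible for n1 + n2 <= ~16.
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # two-sided: tables at least as extreme in distance from the null mean
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two samples. Small
#' samples (`n1 + n2 <= 16`) use exact enumeration over all rank
#' assignments (valid with ties, via midranks); larger samples use the
#' normal approximation with tie correction.
#'
#' @param x,y numeric samples, both non-empty.
#' @return List with `U` (number of `(x, y)` pairs with `x > y`, ties
#'   counting one half), `p` (two-sided), `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 16) {
    return(list(U = u, p = mwu_exact_p(x, y), method = "exact"))
  }
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 == 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(U = u, p = 2 * pnorm(-abs(z)), method = "normal")
}

# split a genotype vector into two strata per a grouping rule
genotype_strata <- function(g, grouping, labels) {
  switch(grouping,
    dominant = list(
      g1 = which(g == 0L), g2 = which(g >= 1L),
      lab1 = labels["hom_ref"],
      lab2 = paste0(labels["het"], "+", labels["hom_alt"])),
    recessive = list(
      g1 = which(g <= 1L), g2 = which(g == 2L),
      lab1 = paste0(labels["hom_ref"], "+", labels["het"]),
      lab2 = labels["hom_alt"]),
    het_vs_hom_ref = list(
      g1 = which(g == 0L), g2 = which(g == 1L),
      lab1 = labels["hom_ref"], lab2 = labels["het"]),
    stop("unknown grouping: ", grouping)
  )
}

#' Genotype-stratified quantitative-trait comparison
#'
#' Compares a quantitative trait between genotype strata of one SNP, within
#' cases, controls, or the whole cohort. Subjects missing the trait or the
#' genotype are excluded and counted.
#'
#' @param ds a [cohort_dataset()].
#' @param snp_id rsID present in `ds`.
#' @param trait name of a numeric column of `ds$pheno`.
#' @param grouping `"dominant"` (homRef vs carriers), `"recessive"`, or
#'   `"het_vs_hom_ref"`.
#' @param within `"all"`, `"case"`, or `"control"`.
#' @param test `"student"`, `"welch"`, or `"mann_whitney"`.
#' @return List of class `trait_comparison`: group labels, per-group n,
#'   mean, sd, the test statistic and two-sided p, and the number of
#'   excluded subjects. The statistic is positive when the second stratum
#'   (variant carriers) has the larger mean.
#' @export
trait_by_genotype <- function(ds, snp_id, trait,
                              grouping = c("dominant", "recessive",
                                           "het_vs_hom_ref"),
                              within = c("all", "case", "control"),
                              test = c("student", "welch", "mann_whitney")) {
  grouping <- match.arg(grouping)
  within <- match.arg(within)
  test <- match.arg(test)
  stopifnot(inherits(ds, "cohort_dataset"))
  if (!snp_id %in% colnames(ds$geno)) stop("unknown snp_id: ", snp_id)
  if (!trait %in% names(ds$pheno)) stop("unknown trait: ", trait)

  keep <- if (within == "all") rep(TRUE, nrow(ds$pheno))
          else ds$pheno$status == within
  g <- ds$geno[keep, snp_id]
  v <- ds$pheno[[trait]][keep]
  ok <- !is.na(g) & !is.na(v)
  n_excluded <- sum(!ok)
  g <- g[ok]; v <- v[ok]

  st <- genotype_strata(g, grouping, genotype_labels(ds$snps[[snp_id]]))
  x1 <- v[st$g1]; x2 <- v[st$g2]
  if (length(x1) < 2 || length(x2) < 2)
    stop("stratum '", if (length(x1) < 2) st$lab1 else st$lab2,
         "' has fewer than 2 subjects with trait ", trait)

  if (test == "mann_whitney") {
    mw <- mann_whitney_u(x1, x2)
    stat <- mw$U; p <- mw$p
  } else {
    tt <- t_test_summary(mean(x1), sd(x1), length(x1),
                         mean(x2), sd(x2), length(x2), variant = test)
    stat <- tt$t; p <- tt$p
  }
  structure(list(
    snp_id = snp_id, trait = trait, grouping = grouping, within = within,
    test = test, group1 = unname(st$lab1), group2 = unname(st$lab2),
    n1 = length(x1), n2 = length(x2),
    mean1 = mean(x1), sd1 = sd(x1), mean2 = mean(x2), sd2 = sd(x2),
    statistic = stat, p = p, n_excluded = n_excluded),
    class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf("<trait_comparison> %s by %s (%s, within %s)\n", x$trait,
              x$snp_id, x$grouping, x$within))
  cat(sprintf("  %s: %.3f +/- %.3f (n=%d)   %s: %.3f +/- %.3f (n=%d)\n",
              x$group1, x$mean1, x$sd1, x$n1,
              x$group2, x$mean2, x$sd2, x$n2))
  cat(sprintf("  %s: statistic = %.3f, p = %.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}
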