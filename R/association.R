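#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with cells `a` (exposed cases), `b` (unexposed cases),
#' `c` (exposed controls) and `d` (unexposed controls), computes
#' `OR = ad/(bc)` with the Woolf interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' If exactly one cell is zero, the Haldane-Anscombe correction (+0.5 to all
#' four cells) is applied before estimation. A table with an all-zero margin,
#' or with two or more zero cells, has no usable OR and is an error.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alpha two-sided confidence level is `1 - alpha` (default 95%).
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`, and
#'   `corrected` (whether the +0.5 correction was used).
#' @examples
#' odds_ratio_woolf(86, 314, 39, 361)  # allelic OR 2.54 (1.69-3.81)
#' @export
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("odds ratio undefined: a margin of the 2x2 table is zero")
  nz <- sum(cells == 0)
  if (nz >= 2)
    stop("odds ratio undefined: ", nz, " zero cells in the 2x2 table")
  corrected <- nz == 1
  if (corrected) cells <- cells + 0.5
  lor <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  list(or = unname(exp(lor)),
       ci_low = unname(exp(lor - z * se)),
       ci_high = unname(exp(lor + z * se)),
       log_or = unname(lor), se_log_or = unname(se), corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without Yates continuity correction (df = 1), matching the convention used
#' for the allele- and genotype-frequency comparisons in this package.
#'
#' @inheritParams odds_ratio_woolf
#' @return List with `chi2` and `p`.
#' @export
chi2_test_2x2 <- function(a, b, c, d) {
  cells <- as.numeric(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- sum(cells)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0)
    stop("chi-square test undefined: a margin of the 2x2 table is zero")
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities that do not exceed the observed table's probability.
#'
#' @inheritParams odds_ratio_woolf
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * p_values)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with the expectations `n p^2`, `2npq`,
#' `n q^2` at the observed allele frequency (1 df).
#'
#' @param gc a [genotype_counts()] object.
#' @param alpha significance level for the `in_hwe` flag.
#' @return List with `snp_id`, `group`, `chi2`, `df`, `p`, `in_hwe`, and the
#'   expected counts.
#' @examples
#' hwe_chi2(genotype_counts("rs731236", "control", 77, 58, 65))
#' @export
hwe_chi2 <- function(gc, alpha = 0.05) {
  stopifnot(inherits(gc, "genotype_counts"))
  if (gc$n_total == 0L) stop("HWE undefined: no subjects for ", gc$snp_id)
  q <- allele_frequency(gc)
  if (q == 0 || q == 1)
    stop("HWE undefined for monomorphic SNP ", gc$snp_id, " (", gc$group, ")")
  p <- 1 - q
  expected <- gc$n_total * c(hom_ref = p^2, het = 2 * p * q, hom_alt = q^2)
  observed <- c(gc$n_hom_ref, gc$n_het, gc$n_hom_alt)
  chi2 <- sum((observed - expected)^2 / expected)
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(snp_id = gc$snp_id, group = gc$group, chi2 = chi2, df = 1L,
       p = pval, in_hwe = pval >= alpha, expected = expected)
}

genotype_labels <- function(snp) {
  if (is.null(snp))
    c(hom_ref = "homRef", het = "het", hom_alt = "homAlt")
  else c(hom_ref = paste0(snp$ref_allele, snp$ref_allele),
         het = paste0(snp$ref_allele, snp$alt_allele),
         hom_alt = paste0(snp$alt_allele, snp$alt_allele))
}

# run one 2x2 contrast (exposed-vs-reference) through OR + test selection
contrast_2x2 <- function(snp_id, model, contrast, a, b, c, d) {
  n <- a + b + c + d
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  test_used <- if (any(expected < 5)) "fisher" else "chi2"
  p <- if (test_used == "fisher") fisher_exact_2x2(a, b, c, d)
       else chi2_test_2x2(a, b, c, d)$p
  orw <- odds_ratio_woolf(a, b, c, d)
  data.frame(snp_id = snp_id, model = model, contrast = contrast,
             a = a, b = b, c = c, d = d,
             or = orw$or, ci_low = orw$ci_low, ci_high = orw$ci_high,
             p_raw = p, test_used = test_used,
             stringsAsFactors = FALSE)
}

#' Genetic-model association contrasts for one SNP
#'
#' Builds the 2x2 table(s) implied by a genetic model and returns Woolf odds
#' ratios with the chi-square p-value, or the Fisher exact p-value when any
#' expected cell is below 5 (the classic rule).
#'
#' Models: `"allelic"` compares alt vs ref allele counts; `"genotypic"`
#' returns het-vs-homRef and homAlt-vs-homRef; `"dominant"` compares carriers
#' (het + homAlt) vs homRef; `"recessive"` compares homAlt vs (homRef + het).
#' A contrast whose exposed genotype class is empty in both groups (e.g. no
#' homozygous-variant subjects anywhere) is omitted with a message, mirroring
#' a blank table cell.
#'
#' @param case,control [genotype_counts()] for the two groups.
#' @param model one or more of `"allelic"`, `"genotypic"`, `"dominant"`,
#'   `"recessive"`.
#' @param snp optional [snp_def()] used only to spell contrast labels with
#'   real alleles (e.g. `"GG vs GT+TT"`).
#' @return Data frame with one row per contrast: OR, 95% CI, raw p, test
#'   used, and the four cells.
#' @examples
#' cc <- ksd_counts()[["rs1801725"]]
#' model_contrasts(cc$case, cc$control, "dominant", snp = ksd_snps()[["rs1801725"]])
#' @export
model_contrasts <- function(case, control,
                            model = c("allelic", "genotypic", "dominant",
                                      "recessive"),
                            snp = NULL) {
  stopifnot(inherits(case, "genotype_counts"),
            inherits(control, "genotype_counts"),
            identical(case$snp_id, control$snp_id))
  model <- match.arg(model, several.ok = TRUE)
  lab <- genotype_labels(snp)
  al <- if (is.null(snp)) c(ref = "ref", alt = "alt")
        else c(ref = snp$ref_allele, alt = snp$alt_allele)
  id <- case$snp_id
  rows <- list()
  skip <- function(contrast)
    message("model_contrasts: ", id, " ", contrast,
            " omitted (empty exposed class)")

  for (mdl in model) {
    if (mdl == "allelic") {
      ca <- allele_counts(case); co <- allele_counts(control)
      if (ca["n_alt"] + co["n_alt"] == 0) { skip("allelic"); next }
      rows[[length(rows) + 1L]] <- contrast_2x2(
        id, "allelic", paste(al["alt"], "vs", al["ref"]),
        ca[["n_alt"]], ca[["n_ref"]], co[["n_alt"]], co[["n_ref"]])
    } else if (mdl == "genotypic") {
      for (cls in c("het", "hom_alt")) {
        a <- case[[paste0("n_", cls)]]; c_ <- control[[paste0("n_", cls)]]
        contrast <- paste(lab["hom_ref"], "vs", lab[cls])
        if (a + c_ == 0) { skip(contrast); next }
        rows[[length(rows) + 1L]] <- contrast_2x2(
          id, "genotypic", contrast, a, case$n_hom_ref, c_, control$n_hom_ref)
      }
    } else if (mdl == "dominant") {
      a <- case$n_het + case$n_hom_alt
      c_ <- control$n_het + control$n_hom_alt
      contrast <- paste0(lab["hom_ref"], " vs ", lab["het"], "+", lab["hom_alt"])
      if (a + c_ == 0) { skip(contrast); next }
      rows[[length(rows) + 1L]] <- contrast_2x2(
        id, "dominant", contrast, a, case$n_hom_ref, c_, control$n_hom_ref)
    } else if (mdl == "recessive") {
      a <- case$n_hom_alt; c_ <- control$n_hom_alt
      contrast <- paste0(lab["hom_ref"], "+", lab["het"], " vs ", lab["hom_alt"])
      if (a + c_ == 0) { skip(contrast); next }
      rows[[length(rows) + 1L]] <- contrast_2x2(
        id, "recessive", contrast, a, case$n_hom_ref + case$n_het,
        c_, control$n_hom_ref + control$n_het)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), model = character(),
                      contrast = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_raw = numeric(), test_used = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Association sweep over a count fixture
#'
#' Runs [model_contrasts()] for every SNP in a count table (such as
#' [ksd_counts()]) under all four genetic models and applies a Bonferroni
#' correction across SNPs.
#'
#' @param counts named list keyed by rsID, each element a list with `case`
#'   and `control` [genotype_counts()].
#' @param snps optional named list of [snp_def()] for allele-spelled labels.
#' @param m Bonferroni denominator; defaults to the number of SNPs in
#'   `counts`.
#' @param models genetic models to run.
#' @return Data frame, one row per SNP x contrast, with `p_bonferroni` added.
#' @examples
#' sweep <- association_sweep(ksd_counts(), ksd_snps())
#' subset(sweep, model == "allelic")
#' @export
association_sweep <- function(counts, snps = NULL, m = length(counts),
                              models = c("allelic", "genotypic", "dominant",
                                         "recessive")) {
  res <- lapply(names(counts), function(id) {
    model_contrasts(counts[[id]]$case, counts[[id]]$control, models,
                    snp = snps[[id]])
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- bonferroni(out$p_raw, m = m)
  out
}
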