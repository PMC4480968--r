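# binary exposure coding implied by a genetic contrast; NA = subject excluded
exposure_from_genotype <- function(g, contrast) {
  switch(contrast,
    dominant  = ifelse(is.na(g), NA, as.integer(g >= 1L)),
    recessive = ifelse(is.na(g), NA, as.integer(g == 2L)),
    het       = ifelse(is.na(g) | g == 2L, NA, as.integer(g == 1L)),
    hom_alt   = ifelse(is.na(g) | g == 1L, NA, as.integer(g == 2L)),
    allelic   = stop("allelic contrast has no per-subject binary coding; ",
                     "use model_contrasts on allele counts"),
    stop("unknown contrast: ", contrast)
  )
}

#' Covariate-adjusted odds ratio for a genotype contrast
#'
#' Fits a binary-outcome logistic regression of case status on a binary
#' genotype exposure plus covariates, via iteratively reweighted least
#' squares ([stats::glm()] with the binomial family). The adjusted OR is the
#' exponentiated exposure coefficient with a Wald 95% interval.
#'
#' Contrasts: `"dominant"` (carrier of >= 1 alt allele vs homRef),
#' `"recessive"` (homAlt vs the rest), `"het"` and `"hom_alt"` (each vs
#' homRef, other subjects excluded). Subjects missing the genotype or any
#' covariate are excluded and reported in `n_used`. Complete or
#' quasi-complete separation is flagged (`converged = FALSE`) rather than
#' reported as a finite estimate.
#'
#' @param ds a [cohort_dataset()].
#' @param snp_id rsID present in `ds`.
#' @param contrast exposure coding, see Details.
#' @param covariates character vector of `ds$pheno` column names; sex is
#'   recoded 0/1 (female/male) if character. Use `character(0)` for a crude
#'   (unadjusted) fit.
#' @param alpha 1 - confidence level.
#' @return List of class `adjusted_or`: `or_adj`, `ci_low`, `ci_high`, `p`,
#'   `converged`, `n_used`, `covariates`, `fit`.
#' @export
adjusted_or <- function(ds, snp_id, contrast = "dominant",
                        covariates = c("age", "sex", "bmi"), alpha = 0.05) {
  stopifnot(inherits(ds, "cohort_dataset"))
  if (!snp_id %in% colnames(ds$geno)) stop("unknown snp_id: ", snp_id)
  miss <- setdiff(covariates, names(ds$pheno))
  if (length(miss)) stop("covariate(s) absent from pheno: ",
                         paste(miss, collapse = ", "))

  dat <- data.frame(
    y = as.integer(ds$pheno$status == "case"),
    exposure = exposure_from_genotype(ds$geno[, snp_id], contrast))
  for (cv in covariates) {
    v <- ds$pheno[[cv]]
    if (cv == "sex" && !is.numeric(v)) v <- as.integer(v == "male")
    dat[[cv]] <- v
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (min(table(factor(dat$y, levels = 0:1))) < 2)
    stop("fewer than 2 subjects in an outcome class after exclusions")
  if (length(unique(dat$exposure)) < 2)
    stop("exposure is constant after exclusions; no contrast to estimate")

  fit <- glm(y ~ ., data = dat, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  beta <- coef(fit)["exposure"]
  se <- sqrt(vcov(fit)["exposure", "exposure"])
  # quasi-complete separation shows as runaway coefficient / huge Wald SE
  separated <- !fit$converged || abs(beta) > 15 || se > 100
  z <- qnorm(1 - alpha / 2)
  structure(list(
    snp_id = snp_id, contrast = contrast,
    or_adj = if (separated) NA_real_ else unname(exp(beta)),
    ci_low = if (separated) NA_real_ else unname(exp(beta - z * se)),
    ci_high = if (separated) NA_real_ else unname(exp(beta + z * se)),
    p = if (separated) NA_real_
        else unname(2 * pnorm(-abs(beta / se))),
    converged = !separated, n_used = nrow(dat),
    covariates = covariates, fit = fit), class = "adjusted_or")
}

#' @export
print.adjusted_or <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<adjusted_or> %s [%s] OR = %.2f (%.2f-%.2f), p = %.3g, n = %d\n",
                x$snp_id, x$contrast, x$or_adj, x$ci_low, x$ci_high, x$p,
                x$n_used))
  else
    cat(sprintf("<adjusted_or> %s [%s] did not converge (separation?) n = %d\n",
                x$snp_id, x$contrast, x$n_used))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
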