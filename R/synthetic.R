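#' Specify a synthetic case-control cohort
#'
#' A `cohort_spec` describes the statistical structure of a cohort to be
#' drawn by [generate_cohort()]: group sizes, per-SNP genotype distributions
#' (either exact per-group counts or alt-allele frequencies with
#' Hardy-Weinberg sampling), optional pairwise LD targets, and normal trait
#' models per stratum.
#'
#' @param n_case,n_control group sizes.
#' @param snps named list of [snp_def()].
#' @param counts named list (by rsID) of lists with `case`/`control`
#'   [genotype_counts()]: exact-marginal mode for those SNPs. Counts must
#'   sum to the group sizes.
#' @param freqs named list (by rsID) of lists with numeric `case`/`control`
#'   alt-allele frequencies in (0, 1): HWE sampling mode.
#' @param ld_targets optional data frame with columns `snp1`, `snp2`, `r2`:
#'   target pairwise r2 for frequency-mode SNP pairs (positive-D
#'   convention). SNPs not named in any pair are sampled independently.
#' @param trait_models list of trait models. Each element is named by the
#'   trait and is either `list(case = c(mean, sd), control = c(mean, sd))`
#'   (group-level) or additionally stratified by carrier status at one SNP:
#'   `list(snp_id =, case = list(non_carrier = c(mean, sd), carrier =
#'   c(mean, sd)), control = ...)`. Stratified models take precedence over
#'   group-level models for the same trait.
#' @param covariate_models list with optional elements `age`, `bmi` (each
#'   `list(case = c(mean, sd), control = c(mean, sd))`) and `sex_male`
#'   (`list(case = p, control = p)` probability of male).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case, n_control, snps, counts = NULL, freqs = NULL,
                        ld_targets = NULL, trait_models = list(),
                        covariate_models = list()) {
  stopifnot(n_case >= 1, n_control >= 1, is.list(snps))
  for (id in names(counts)) {
    cc <- counts[[id]]
    if (cc$case$n_total != n_case || cc$control$n_total != n_control)
      stop("exact counts for ", id, " do not sum to the group sizes")
  }
  for (id in names(freqs)) {
    fr <- unlist(freqs[[id]])
    if (any(fr <= 0 | fr >= 1))
      stop("allele frequencies for ", id, " must lie in (0, 1)")
  }
  overlap <- intersect(names(counts), names(freqs))
  if (length(overlap))
    stop("SNP(s) given both counts and frequencies: ",
         paste(overlap, collapse = ", "))
  if (!is.null(ld_targets)) {
    stopifnot(all(c("snp1", "snp2", "r2") %in% names(ld_targets)))
    in_counts <- c(ld_targets$snp1, ld_targets$snp2) %in% names(counts)
    if (any(in_counts))
      stop("LD targets are only supported for frequency-mode SNPs")
  }
  structure(list(n_case = n_case, n_control = n_control, snps = snps,
                 counts = counts, freqs = freqs, ld_targets = ld_targets,
                 trait_models = trait_models,
                 covariate_models = covariate_models),
            class = "cohort_spec")
}

# haplotype frequencies achieving a target r2 (positive D) at given
# alt-allele frequencies; errors if infeasible.
haps_for_r2 <- function(pA, pB, r2) {
  d_max <- min(pA * (1 - pB), (1 - pA) * pB)
  r2_max <- d_max^2 / (pA * (1 - pA) * pB * (1 - pB))
  if (r2 > r2_max + 1e-12)
    stop(sprintf("target r2 %.3f infeasible at frequencies %.3f/%.3f (max %.3f)",
                 r2, pA, pB, r2_max))
  D <- sqrt(r2 * pA * (1 - pA) * pB * (1 - pB))
  c(rr = (1 - pA) * (1 - pB) + D, ra = (1 - pA) * pB - D,
    ar = pA * (1 - pB) - D, aa = pA * pB + D)
}

sample_trait <- function(n, ms) rnorm(n, ms[1], ms[2])

#' Generate a synthetic cohort
#'
#' Draws a [cohort_dataset()] from a [cohort_spec()]. Exact-count SNPs are
#' assigned by a seeded permutation within each group, so their per-group
#' genotype counts match the spec exactly and every count-based statistic is
#' invariant to the seed. Frequency-mode SNPs are sampled under
#' Hardy-Weinberg proportions, independently across SNPs unless an LD
#' target links a pair, in which case genotype pairs are built from two
#' sampled haplotypes at the implied haplotype frequencies. Traits and
#' covariates are drawn from their normal (or Bernoulli) models per stratum.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the draw is fully reproducible.
#' @return A [cohort_dataset()].
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_case + spec$n_control
  status <- c(rep("case", spec$n_case), rep("control", spec$n_control))
  ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- unique(c(names(spec$counts), names(spec$freqs)))
  geno <- matrix(NA_integer_, n, length(snp_ids),
                 dimnames = list(ids, snp_ids))

  # exact-marginal SNPs: permute the fixed genotype multiset within group
  for (id in names(spec$counts)) {
    for (grp in c("case", "control")) {
      gc <- spec$counts[[id]][[grp]]
      pool <- rep(0:2, times = c(gc$n_hom_ref, gc$n_het, gc$n_hom_alt))
      geno[status == grp, id] <- sample(pool)
    }
  }

  # LD-linked frequency-mode pairs: genotypes from sampled haplotype pairs
  done <- character()
  if (!is.null(spec$ld_targets)) {
    for (i in seq_len(nrow(spec$ld_targets))) {
      s1 <- spec$ld_targets$snp1[i]; s2 <- spec$ld_targets$snp2[i]
      if (s1 %in% done || s2 %in% done)
        stop("SNP appears in more than one LD target pair")
      for (grp in c("case", "control")) {
        f <- haps_for_r2(spec$freqs[[s1]][[grp]], spec$freqs[[s2]][[grp]],
                         spec$ld_targets$r2[i])
        ng <- sum(status == grp)
        # haplotype index 1..4 = rr, ra, ar, aa; two independent draws
        h1 <- sample.int(4, ng, replace = TRUE, prob = f)
        h2 <- sample.int(4, ng, replace = TRUE, prob = f)
        alt1 <- c(0L, 0L, 1L, 1L)
        alt2 <- c(0L, 1L, 0L, 1L)
        geno[status == grp, s1] <- alt1[h1] + alt1[h2]
        geno[status == grp, s2] <- alt2[h1] + alt2[h2]
      }
      done <- c(done, s1, s2)
    }
  }

  # remaining frequency-mode SNPs: independent HWE sampling
  for (id in setdiff(names(spec$freqs), done)) {
    for (grp in c("case", "control")) {
      p <- spec$freqs[[id]][[grp]]
      geno[status == grp, id] <- rbinom(sum(status == grp), 2L, p)
    }
  }

  pheno <- data.frame(subject_id = ids, status = status,
                      stringsAsFactors = FALSE)
  cm <- spec$covariate_models
  for (cv in c("age", "bmi")) {
    if (!is.null(cm[[cv]])) {
      pheno[[cv]] <- NA_real_
      for (grp in c("case", "control"))
        pheno[[cv]][status == grp] <-
          sample_trait(sum(status == grp), cm[[cv]][[grp]])
    }
  }
  if (!is.null(cm$sex_male)) {
    pheno$sex <- NA_character_
    for (grp in c("case", "control"))
      pheno$sex[status == grp] <-
        ifelse(runif(sum(status == grp)) < cm$sex_male[[grp]],
               "male", "female")
  }

  for (trait in names(spec$trait_models)) {
    tm <- spec$trait_models[[trait]]
    pheno[[trait]] <- NA_real_
    if (!is.null(tm$snp_id)) {
      carrier <- geno[, tm$snp_id] >= 1L
      for (grp in c("case", "control")) {
        for (cls in c("non_carrier", "carrier")) {
          sel <- status == grp & !is.na(carrier) &
            (carrier == (cls == "carrier"))
          pheno[[trait]][sel] <- sample_trait(sum(sel), tm[[grp]][[cls]])
        }
        # missing genotype at the stratifying SNP: group-level fallback
        sel <- status == grp & is.na(carrier)
        if (any(sel) && !is.null(tm$fallback))
          pheno[[trait]][sel] <- sample_trait(sum(sel), tm$fallback[[grp]])
      }
    } else {
      for (grp in c("case", "control"))
        pheno[[trait]][status == grp] <-
          sample_trait(sum(status == grp), tm[[grp]])
    }
  }
  cohort_dataset(spec$snps[snp_ids], pheno, geno)
}

#' Synthetic reference cohort with exact genotype marginals
#'
#' Builds the 200-case/200-control cohort that this package's count tables
#' describe: per-SNP genotype counts equal [ksd_counts()] exactly for all
#' eight SNPs (so every count-based statistic reproduces the reference
#' tables regardless of seed), covariates and traits drawn from the reported
#' group means and standard deviations, and serum/urinary calcium
#' additionally stratified by rs1801725 / rs1042636 carrier status with the
#' reported stratum models.
#'
#' Joint genotypes across SNPs are assigned independently: the source count
#' tables are per-SNP marginals only, so multi-locus statistics (combined
#' carrier ORs, dosage categories) are exercised as procedures here, not
#' reproduced as published values.
#'
#' @param seed integer seed for the subject-level assignment.
#' @return A [cohort_dataset()] with 400 subjects and 8 SNPs.
#' @export
ksd_cohort <- function(seed = 1L) {
  trait_models <- list(
    serum_calcium = list(
      snp_id = "rs1801725",
      case = list(non_carrier = c(9.20, 0.20), carrier = c(9.72, 0.18)),
      control = list(non_carrier = c(9.45, 0.21), carrier = c(9.64, 0.25)),
      fallback = list(case = c(9.42, 0.32), control = c(9.46, 0.238))),
    urinary_calcium = list(
      snp_id = "rs1042636",
      case = list(non_carrier = c(7.58, 0.57), carrier = c(8.10, 0.51)),
      control = list(non_carrier = c(4.04, 0.71), carrier = c(4.02, 0.62)),
      fallback = list(case = c(7.87, 0.59), control = c(4.04, 0.68))),
    serum_creatinine = list(case = c(1.21, 0.477), control = c(0.714, 0.096)),
    urinary_oxalate = list(case = c(28.11, 3.07), control = c(27.51, 3.11)),
    urinary_citrate = list(case = c(2.58, 0.96), control = c(2.77, 1.21)),
    urinary_potassium = list(case = c(64.21, 4.77), control = c(64.59, 4.61)),
    urinary_phosphate = list(case = c(27.45, 4.29), control = c(26.81, 3.33)),
    urinary_urate = list(case = c(2.89, 0.47), control = c(2.78, 0.86)),
    urine_ph = list(case = c(5.72, 0.31), control = c(5.79, 0.55)))
  spec <- cohort_spec(
    n_case = 200, n_control = 200, snps = ksd_snps(),
    counts = ksd_counts(),
    trait_models = trait_models,
    covariate_models = list(
      age = list(case = c(39.93, 11.37), control = c(38.13, 10.16)),
      bmi = list(case = c(22.11, 1.19), control = c(22.20, 1.34)),
      sex_male = list(case = 0.665, control = 0.610)))
  generate_cohort(spec, seed = seed)
}
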