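#' Display-layer formatting helpers
#'
#' `format_or_ci()` renders an odds ratio with its CI to 2 decimals;
#' `format_p()` renders p-values to 3 decimals with a `"<0.001"` floor.
#' Full precision is always retained in the underlying data frames; these
#' helpers exist only for report output.
#'
#' @param or,ci_low,ci_high numeric estimate and interval.
#' @return Character vector.
#' @export
format_or_ci <- function(or, ci_low, ci_high) {
  ifelse(is.na(or), "",
         sprintf("%.2f (%.2f-%.2f)", or, ci_low, ci_high))
}

#' @rdname format_or_ci
#' @param p numeric p-values.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full candidate-gene analysis and write a report bundle
#'
#' Orchestrates the whole pipeline on one cohort: per-SNP genotype counts,
#' allelic and genotype-model association with Bonferroni correction,
#' Hardy-Weinberg checks in both groups, pairwise LD (cases and controls
#' separately), covariate-adjusted odds ratios, the effective-risk-allele
#' dosage analysis, and genotype-stratified trait comparisons. Each stage is
#' written as a TSV table, with a JSON summary and a run log alongside.
#' Output is deterministic given the dataset and seed; on any stage failure
#' the partial output directory is removed and the stage name is reported.
#'
#' @param ds a [cohort_dataset()].
#' @param outdir output directory (created; must not be an existing
#'   non-empty directory unless `overwrite = TRUE`).
#' @param snp_ids SNPs to analyse; default all in `ds`. Unknown IDs abort
#'   before any computation.
#' @param m Bonferroni denominator; defaults to the number of SNPs analysed.
#' @param covariates covariate set for adjusted ORs; set `NULL` to skip the
#'   adjustment stage.
#' @param weights [dosage_weights()] for the dosage stage; `NULL` skips it.
#' @param trait_specs list of lists with fields `trait`, `snp_id`,
#'   `grouping`, `within` (and optionally `test`) for the traits stage.
#' @param seed recorded in the log; the analysis itself is deterministic.
#' @param overwrite allow writing into an existing directory.
#' @return Invisibly, a named list of the files written.
#' @export
run_full_analysis <- function(ds, outdir, snp_ids = colnames(ds$geno),
                              m = length(snp_ids),
                              covariates = c("age", "sex", "bmi"),
                              weights = NULL,
                              trait_specs = list(),
                              seed = 1L, overwrite = FALSE) {
  stopifnot(inherits(ds, "cohort_dataset"))
  unknown <- setdiff(snp_ids, colnames(ds$geno))
  if (length(unknown))
    stop("config names SNP(s) absent from the dataset: ",
         paste(unknown, collapse = ", "))
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop("output directory exists and is not empty: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- "setup"

  res <- tryCatch({
    counts <- lapply(setNames(snp_ids, snp_ids), counts_from_dataset,
                     ds = ds)

    stage <- "association"
    assoc <- association_sweep(counts, snps = ds$snps[snp_ids], m = m)
    assoc$or_ci <- format_or_ci(assoc$or, assoc$ci_low, assoc$ci_high)
    assoc$p_display <- format_p(assoc$p_raw)
    files$assoc_allelic <- write_tsv(assoc[assoc$model == "allelic", ],
                                     file.path(outdir, "assoc_allelic.tsv"))
    files$assoc_genotypic <- write_tsv(assoc[assoc$model != "allelic", ],
                                       file.path(outdir,
                                                 "assoc_genotypic.tsv"))

    stage <- "hwe"
    hwe <- do.call(rbind, lapply(snp_ids, function(id) {
      do.call(rbind, lapply(c("case", "control"), function(grp) {
        h <- tryCatch(hwe_chi2(counts[[id]][[grp]]),
                      error = function(e) NULL)
        if (is.null(h)) return(NULL)
        data.frame(snp_id = id, group = grp, chi2 = h$chi2, p = h$p,
                   in_hwe = h$in_hwe, stringsAsFactors = FALSE)
      }))
    }))
    files$hwe <- write_tsv(hwe, file.path(outdir, "hwe.tsv"))

    stage <- "ld"
    ld_rows <- do.call(rbind, lapply(c("case", "control"), function(grp) {
      r2 <- ld_matrix(ds, snp_ids, group = grp)
      idx <- which(upper.tri(r2), arr.ind = TRUE)
      data.frame(group = grp, snp1 = rownames(r2)[idx[, 1]],
                 snp2 = colnames(r2)[idx[, 2]], r2 = r2[idx],
                 stringsAsFactors = FALSE)
    }))
    files$ld <- write_tsv(ld_rows, file.path(outdir, "ld.tsv"))

    stage <- "adjustment"
    if (!is.null(covariates) &&
        all(covariates %in% names(ds$pheno))) {
      adj <- do.call(rbind, lapply(snp_ids, function(id) {
        a <- tryCatch(adjusted_or(ds, id, "dominant", covariates),
                      error = function(e) NULL)
        if (is.null(a)) return(NULL)
        data.frame(snp_id = id, contrast = "dominant",
                   or_adj = a$or_adj, ci_low = a$ci_low,
                   ci_high = a$ci_high, p = a$p, converged = a$converged,
                   n_used = a$n_used, stringsAsFactors = FALSE)
      }))
      files$adjusted <- write_tsv(adj, file.path(outdir, "adjusted.tsv"))
    }

    stage <- "dosage"
    if (!is.null(weights)) {
      dr <- dosage_category_analysis(ds, weights)
      files$dosage <- write_tsv(dr$categories,
                                file.path(outdir, "dosage.tsv"))
    }

    stage <- "traits"
    if (length(trait_specs)) {
      tr <- do.call(rbind, lapply(trait_specs, function(sp) {
        tc <- do.call(trait_by_genotype, c(list(ds = ds), sp))
        data.frame(trait = tc$trait, snp_id = tc$snp_id,
                   grouping = tc$grouping, within = tc$within,
                   group1 = tc$group1, n1 = tc$n1, mean1 = tc$mean1,
                   sd1 = tc$sd1, group2 = tc$group2, n2 = tc$n2,
                   mean2 = tc$mean2, sd2 = tc$sd2,
                   statistic = tc$statistic, p = tc$p,
                   stringsAsFactors = FALSE)
      }))
      files$traits <- write_tsv(tr, file.path(outdir, "traits.tsv"))
    }

    stage <- "summary"
    summary <- list(
      n_case = sum(ds$pheno$status == "case"),
      n_control = sum(ds$pheno$status == "control"),
      snps = snp_ids, bonferroni_m = m, seed = seed,
      n_association_rows = nrow(assoc),
      n_significant_bonferroni = sum(assoc$p_bonferroni < 0.05))
    files$summary <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    log_lines <- c(
      paste("stonekit", as.character(utils::packageVersion("stonekit"))),
      paste("R", paste(R.version$major, R.version$minor, sep = ".")),
      paste("seed", seed),
      paste("snps", paste(snp_ids, collapse = ",")),
      paste("stages", paste(names(files), collapse = ",")))
    files$log <- file.path(outdir, "run.log")
    writeLines(log_lines, files$log)
    files
  }, error = function(e) {
    unlink(outdir, recursive = TRUE)
    stop("analysis failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
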