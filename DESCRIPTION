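Package: stonekit
Title: Candidate-Gene Case-Control Association Analysis for Kidney Stone
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene case-control association studies of
    calcium kidney stone disease: allelic, genotypic, dominant and recessive
    odds ratios with Woolf confidence intervals, chi-square and Fisher exact
    tests, Hardy-Weinberg equilibrium checks, EM-based haplotype frequency
    estimation and pairwise linkage disequilibrium (r2, D'), covariate-adjusted
    odds ratios by logistic regression, a weighted "effective risk allele"
    dosage score with category-wise risk estimates, and genotype-stratified
    quantitative-trait comparisons. Includes a reference set of genotype
    counts for eight SNPs in CaSR, VDR and CLDN14 from a 200-case/200-control
    kidney-stone cohort and a synthetic-cohort generator that reproduces those
    counts exactly, so the full pipeline is testable without individual-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR
Config/testthat/edition: 3
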