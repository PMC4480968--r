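test_that("Woolf odds ratio and CI reproduce published examples", {
  # allelic, rs1801725: T alleles 86/314 in cases vs 39/361 in controls
  r <- odds_ratio_woolf(86, 314, 39, 361)
  expect_equal(round(r$or, 2), 2.54)
  expect_equal(round(r$ci_low, 2), 1.69)
  expect_equal(round(r$ci_high, 2), 3.81)

  # homozygote contrast with tiny cells, rs1042636 GG vs AA
  r2 <- odds_ratio_woolf(15, 86, 1, 130)
  expect_equal(round(r2$or, 2), 22.67)
  expect_equal(round(r2$ci_low, 2), 2.94)
  expect_equal(round(r2$ci_high, 2), 174.82)

  # balanced table: OR 1, CI symmetric about 1 on the log scale
  r3 <- odds_ratio_woolf(10, 10, 10, 10)
  expect_equal(r3$or, 1)
  expect_equal(log(r3$ci_low), -log(r3$ci_high))
})

test_that("single zero cell triggers the Haldane-Anscombe correction", {
  r <- odds_ratio_woolf(0, 10, 5, 5)
  expect_true(r$corrected)
  expect_equal(r$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(round(r$or, 4), 0.0476)
  expect_error(odds_ratio_woolf(0, 10, 0, 10), "margin")
  expect_error(odds_ratio_woolf(0, 10, 10, 0), "zero cells")
})

test_that("OR antisymmetry: swapping exposure labels inverts the estimate", {
  set.seed(41)
  for (i in 1:25) {
    t <- sample(1:40, 4, replace = TRUE)
    r1 <- odds_ratio_woolf(t[1], t[2], t[3], t[4])
    r2 <- odds_ratio_woolf(t[2], t[1], t[4], t[3])
    expect_equal(r1$or * r2$or, 1, tolerance = 1e-12)
    # CI symmetric about the estimate on the log scale
    expect_equal(log(r1$or) - log(r1$ci_low), log(r1$ci_high) - log(r1$or),
                 tolerance = 1e-12)
  }
})

test_that("chi-square test matches the closed-form 2x2 formula", {
  r <- chi2_test_2x2(86, 314, 39, 361)
  expect_equal(r$chi2, 20.94, tolerance = 0.005)
  expect_lt(r$p, 0.001)
  expect_equal(chi2_test_2x2(10, 10, 10, 10)$chi2, 0)
  expect_equal(chi2_test_2x2(10, 10, 10, 10)$p, 1)
  expect_lt(chi2_test_2x2(64, 336, 32, 368)$p, 0.001 + 1e-12)
  expect_error(chi2_test_2x2(0, 0, 5, 5), "margin")

  set.seed(11)
  for (i in 1:25) {
    t <- sample(1:60, 4, replace = TRUE)
    n <- sum(t)
    manual <- n * (t[1] * t[4] - t[2] * t[3])^2 /
      ((t[1] + t[2]) * (t[3] + t[4]) * (t[1] + t[3]) * (t[2] + t[4]))
    expect_equal(chi2_test_2x2(t[1], t[2], t[3], t[4])$chi2, manual,
                 tolerance = 1e-9)
    # and agrees with the standard implementation sans continuity correction
    ref <- suppressWarnings(
      stats::chisq.test(matrix(t, 2, byrow = TRUE), correct = FALSE))
    expect_equal(chi2_test_2x2(t[1], t[2], t[3], t[4])$chi2,
                 unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("Fisher exact p equals brute-force enumeration for all small tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # rs1801726 allelic alleles, 11/389 vs 10/390: p printed as 1.00
  expect_gt(fisher_exact_2x2(11, 389, 10, 390), 0.99)

  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:40, 1)
    t <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    p_pkg <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(p_pkg, fisher_enum_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    # independent cross-check against the reference implementation
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(p_pkg, ref$p.value, tolerance = 1e-7)
  }
})

test_that("association sweep reproduces the printed ORs and CIs", {
  sweep <- association_sweep(ksd_counts(), ksd_snps())
  # printed crude OR (95% CI) rows that are arithmetically consistent with
  # the genotype counts; rs219777/rs2228570/rs731236 allelic rows and the
  # rs731236 genotype rows are inconsistent in the source and excluded
  golden <- rbind(
    data.frame(snp_id = "rs1801725", model = "allelic",
               or = 2.54, lo = 1.69, hi = 3.81),
    data.frame(snp_id = "rs1042636", model = "allelic",
               or = 2.21, lo = 1.58, hi = 3.07),
    data.frame(snp_id = "rs1801726", model = "allelic",
               or = 1.10, lo = 0.46, hi = 2.63),
    data.frame(snp_id = "rs219778", model = "allelic",
               or = 3.01, lo = 1.82, hi = 4.96),
    data.frame(snp_id = "rs219780", model = "allelic",
               or = 2.19, lo = 1.40, hi = 3.43),
    data.frame(snp_id = "rs1801725", model = "genotypic:GG vs GT",
               or = 3.10, lo = 1.96, hi = 4.88),
    data.frame(snp_id = "rs1801725", model = "genotypic:GG vs TT",
               or = 2.79, lo = 0.25, hi = 31.17),
    data.frame(snp_id = "rs1801725", model = "dominant",
               or = 3.09, lo = 1.97, hi = 4.85),
    data.frame(snp_id = "rs1042636", model = "genotypic:AA vs AG",
               or = 2.17, lo = 1.44, hi = 3.27),
    data.frame(snp_id = "rs1042636", model = "genotypic:AA vs GG",
               or = 22.67, lo = 2.94, hi = 174.82),
    data.frame(snp_id = "rs1042636", model = "recessive",
               or = 16.14, lo = 2.11, hi = 123.37),
    data.frame(snp_id = "rs1801726", model = "genotypic:CC vs CG",
               or = 1.11, lo = 0.46, hi = 2.67),
    data.frame(snp_id = "rs2228570", model = "genotypic:CC vs CT",
               or = 1.61, lo = 1.07, hi = 2.41),
    data.frame(snp_id = "rs2228570", model = "genotypic:CC vs TT",
               or = 0.73, lo = 0.28, hi = 1.95),
    data.frame(snp_id = "rs2228570", model = "dominant",
               or = 1.50, lo = 1.01, hi = 2.24),
    data.frame(snp_id = "rs219777", model = "genotypic:CC vs CT",
               or = 1.66, lo = 0.96, hi = 2.88),
    data.frame(snp_id = "rs219777", model = "genotypic:CC vs TT",
               or = 3.28, lo = 0.34, hi = 31.89),
    data.frame(snp_id = "rs219777", model = "dominant",
               or = 1.73, lo = 1.01, hi = 2.95),
    data.frame(snp_id = "rs219778", model = "genotypic:TT vs TC",
               or = 3.37, lo = 1.95, hi = 5.82),
    data.frame(snp_id = "rs219778", model = "genotypic:TT vs CC",
               or = 3.79, lo = 0.39, hi = 36.80),
    data.frame(snp_id = "rs219778", model = "dominant",
               or = 3.39, lo = 1.98, hi = 5.79),
    data.frame(snp_id = "rs219780", model = "genotypic:GG vs GA",
               or = 2.35, lo = 1.43, hi = 3.85),
    data.frame(snp_id = "rs219780", model = "genotypic:GG vs AA",
               or = 3.65, lo = 0.38, hi = 35.46),
    data.frame(snp_id = "rs219780", model = "dominant",
               or = 2.39, lo = 1.47, hi = 3.89))
  for (i in seq_len(nrow(golden))) {
    g <- golden[i, ]
    if (grepl("^genotypic:", g$model)) {
      contrast <- sub("^genotypic:", "", g$model)
      row <- sweep[sweep$snp_id == g$snp_id & sweep$model == "genotypic" &
                     sweep$contrast == contrast, ]
    } else {
      row <- sweep[sweep$snp_id == g$snp_id & sweep$model == g$model, ]
    }
    expect_identical(nrow(row), 1L, info = paste(g$snp_id, g$model))
    # agreement to the printed 2 decimals: half-unit of the last printed
    # digit, plus a sliver of relative slack for the source's own rounding
    # of wide intervals (123.37 is printed for a value of 123.361)
    tol <- function(v) 0.005 + 5e-4 * abs(v) + 1e-9
    expect_lt(abs(row$or - g$or), tol(g$or),
              label = paste(g$snp_id, g$model, "OR"))
    expect_lt(abs(row$ci_low - g$lo), tol(g$lo),
              label = paste(g$snp_id, g$model, "ci_low"))
    expect_lt(abs(row$ci_high - g$hi), tol(g$hi),
              label = paste(g$snp_id, g$model, "ci_high"))
  }
})

test_that("contrasts with an empty exposed genotype class are omitted", {
  cc <- ksd_counts()[["rs1801726"]]
  expect_message(
    res <- model_contrasts(cc$case, cc$control, snp = ksd_snps()[["rs1801726"]]),
    "omitted")
  expect_false(any(res$contrast == "CC vs GG"))
  expect_false(any(res$model == "recessive"))
  expect_true(any(res$contrast == "CC vs CG"))
})

test_that("Fisher path is taken when an expected cell is below 5", {
  # rs219777 TT contrast: 3/159 vs 1/174 -> smallest expected cell ~ 1.9
  cc <- ksd_counts()[["rs219777"]]
  res <- model_contrasts(cc$case, cc$control, "genotypic",
                         snp = ksd_snps()[["rs219777"]])
  expect_identical(res$test_used[res$contrast == "CC vs TT"], "fisher")
  expect_identical(res$test_used[res$contrast == "CC vs CT"], "chi2")
})

test_that("HWE chi-square flags the published departure and only it", {
  h <- hwe_chi2(genotype_counts("rs731236", "control", 77, 58, 65))
  expect_equal(h$chi2, 34.9, tolerance = 0.05)
  expect_false(h$in_hwe)

  h2 <- hwe_chi2(genotype_counts("rs1801725", "control", 162, 37, 1))
  expect_equal(h2$chi2, 0.52, tolerance = 0.01)
  expect_true(h2$in_hwe)

  # exact HWE proportions give chi2 = 0
  h3 <- hwe_chi2(genotype_counts("x", "case", 25, 50, 25))
  expect_equal(h3$chi2, 0)
  expect_equal(h3$p, 1)

  # chi-square verdicts across all control groups: rs731236 departs
  # strongly; rs1042636 also crosses 0.05 (its single GG homozygote against
  # an expectation of 6.3), a borderline departure the 1-df chi-square is
  # known to overcall at small expected counts
  flags <- vapply(ksd_counts(), function(cc) hwe_chi2(cc$control)$in_hwe,
                  logical(1))
  expect_identical(names(flags)[!flags], c("rs1042636", "rs731236"))
  expect_lt(hwe_chi2(ksd_counts()[["rs731236"]]$control)$p, 1e-6)

  expect_error(hwe_chi2(genotype_counts("x", "case", 10, 0, 0)),
               "monomorphic")
})

test_that("HWE statistic is zero exactly at Hardy-Weinberg counts", {
  for (q in c(0.1, 0.3, 0.5)) {
    n <- 400
    gc <- genotype_counts("x", "case", round(n * (1 - q)^2),
                          round(2 * n * q * (1 - q)), round(n * q^2))
    expect_equal(hwe_chi2(gc)$chi2, 0, tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 8), 0.08)
  expect_equal(bonferroni(0.3, m = 8), 1)
  expect_error(bonferroni(0.5, m = 0), "at least 1")
  expect_error(bonferroni(1.5), "must lie")

  # the borderline dominant-model signals do not survive m = 8
  sweep <- association_sweep(ksd_counts(), ksd_snps(), m = 8)
  dom <- sweep[sweep$model == "dominant" &
                 sweep$snp_id %in% c("rs2228570", "rs731236"), ]
  expect_true(all(dom$p_raw < 0.1))
  expect_true(all(dom$p_bonferroni > 0.05))
})
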