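# tiny cohort written to TSV for reader tests
write_toy_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame(2))) {
  gt <- data.frame(
    subject_id = c("A1", "A2", "A3"),
    rs1801725 = c("GG", "GT", "TT"),
    rs1042636 = c("AA", "AG", "--"),
    check.names = FALSE)
  ph <- data.frame(
    subject_id = c("A1", "A2", "A3", "A4"),
    status = c("case", "case", "control", "control"),
    age = c(40, 35, 38, 42),
    sex = c("male", "female", "male", "male"),
    bmi = c(22.1, 21.5, 23.0, 22.8))
  gpath <- file.path(dir, "geno.tsv")
  ppath <- file.path(dir, "pheno.tsv")
  write.table(gt, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ph, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(geno = gpath, pheno = ppath)
}

# brute-force two-sided Fisher p over all tables with the observed margins
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  support <- max(0, r1 - c2):min(r1, c1)
  logp <- function(k) {
    lchoose(c1, k) + lchoose(c2, r1 - k) - lchoose(c1 + c2, r1)
  }
  probs <- exp(vapply(support, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# log-likelihood of 3x3 joint genotype counts at haplotype freqs constrained
# to the observed allele margins, parameterized by f_aa
joint_loglik_at_faa <- function(j, f_aa) {
  n <- sum(j)
  pA <- sum(rowSums(j) * 0:2) / (2 * n)
  pB <- sum(colSums(j) * 0:2) / (2 * n)
  f <- c(rr = 1 - pA - pB + f_aa, ra = pB - f_aa, ar = pA - f_aa, aa = f_aa)
  if (any(f < 0)) return(-Inf)
  rr <- f[1]; ra <- f[2]; ar <- f[3]; aa <- f[4]
  p <- matrix(0, 3, 3)
  p[1, 1] <- rr^2;          p[1, 2] <- 2 * rr * ra;             p[1, 3] <- ra^2
  p[2, 1] <- 2 * rr * ar;   p[2, 2] <- 2 * rr * aa + 2 * ra * ar
  p[2, 3] <- 2 * ra * aa
  p[3, 1] <- ar^2;          p[3, 2] <- 2 * ar * aa;             p[3, 3] <- aa^2
  sum(j[j > 0] * log(p[j > 0]))
}

# grid-search MLE of f_aa given the allele margins (brute-force oracle)
grid_mle_faa <- function(j, grid_n = 20001) {
  n <- sum(j)
  pA <- sum(rowSums(j) * 0:2) / (2 * n)
  pB <- sum(colSums(j) * 0:2) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, joint_loglik_at_faa, numeric(1), j = j)
  grid[which.max(ll)]
}

# draw a random 3x3 joint genotype count table from haplotype frequencies
simulate_joint_counts <- function(n, f) {
  h1 <- sample.int(4, n, replace = TRUE, prob = f)
  h2 <- sample.int(4, n, replace = TRUE, prob = f)
  alt1 <- c(0, 0, 1, 1); alt2 <- c(0, 1, 0, 1)
  g1 <- alt1[h1] + alt1[h2]; g2 <- alt2[h1] + alt2[h2]
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  matrix(as.integer(tab), 3, 3)
}
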