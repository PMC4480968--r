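#' Joint genotype counts for a SNP pair
#'
#' Tabulates subjects by their genotype pair at two SNPs (alt-allele counts
#' 0/1/2 at each locus). Subjects missing either genotype are excluded.
#'
#' @param ds a [cohort_dataset()].
#' @param snp1,snp2 rsIDs present in `ds`.
#' @param group `"case"`, `"control"`, or `"pooled"`.
#' @return 3x3 integer matrix `n[g1 + 1, g2 + 1]`, rows = genotype at `snp1`.
#' @export
joint_genotype_counts <- function(ds, snp1, snp2,
                                  group = c("pooled", "case", "control")) {
  group <- match.arg(group)
  stopifnot(inherits(ds, "cohort_dataset"))
  for (s in c(snp1, snp2))
    if (!s %in% colnames(ds$geno)) stop("unknown snp_id: ", s)
  keep <- if (group == "pooled") rep(TRUE, nrow(ds$pheno))
          else ds$pheno$status == group
  g1 <- ds$geno[keep, snp1]; g2 <- ds$geno[keep, snp2]
  ok <- !is.na(g1) & !is.na(g2)
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  matrix(as.integer(tab), 3, 3, dimnames = list(g1 = 0:2, g2 = 0:2))
}

# genotype-pair cell probabilities under random union of haplotypes.
# f = c(rr, ra, ar, aa): haplotype frequencies, first letter = locus 1 allele.
hap_cell_probs <- function(f) {
  rr <- f[1]; ra <- f[2]; ar <- f[3]; aa <- f[4]
  p <- matrix(0, 3, 3)
  p[1, 1] <- rr^2
  p[1, 2] <- 2 * rr * ra
  p[1, 3] <- ra^2
  p[2, 1] <- 2 * rr * ar
  p[2, 2] <- 2 * rr * aa + 2 * ra * ar  # double heterozygote: both phases
  p[2, 3] <- 2 * ra * aa
  p[3, 1] <- ar^2
  p[3, 2] <- 2 * ar * aa
  p[3, 3] <- aa^2
  p
}

hap_loglik <- function(f, n) {
  p <- hap_cell_probs(f)
  sum(n[n > 0] * log(p[n > 0]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased genotype counts at
#' two biallelic SNPs. Only double heterozygotes carry phase ambiguity; the
#' EM splits their haplotype contribution according to the current frequency
#' estimates. Initialization is at linkage equilibrium of the observed allele
#' frequencies, and the log-likelihood is non-decreasing across iterations.
#'
#' @param j 3x3 matrix of joint genotype counts, as from
#'   [joint_genotype_counts()].
#' @param tol convergence threshold on the maximum absolute change in any
#'   haplotype frequency.
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   last iterate is returned.
#' @return Object of class `ld_result`: `hap_freqs` (named `rr`, `ra`, `ar`,
#'   `aa`; first letter = allele at locus 1, `r` = ref, `a` = alt), `D`,
#'   `D_prime`, `r2`, `em_iterations`, `loglik`, `converged`, `degenerate`
#'   (flat likelihood, estimate pinned at the equilibrium initializer).
#' @examples
#' j <- matrix(0, 3, 3); j[1, 1] <- 40; j[2, 2] <- 20; j[3, 3] <- 40
#' em_haplotype_freqs(j)$r2
#' @export
em_haplotype_freqs <- function(j, tol = 1e-8, max_iter = 1000L) {
  stopifnot(is.matrix(j), all(dim(j) == c(3, 3)))
  if (any(j < 0) || sum(j) == 0) stop("invalid joint genotype counts")
  n <- sum(j)
  # allele margins
  g1 <- rowSums(j); g2 <- colSums(j)
  pA <- sum(g1 * 0:2) / (2 * n)   # alt frequency, locus 1
  pB <- sum(g2 * 0:2) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("haplotype estimation undefined: monomorphic locus")

  f <- c(rr = (1 - pA) * (1 - pB), ra = (1 - pA) * pB,
         ar = pA * (1 - pB), aa = pA * pB)
  ndh <- j[2, 2]                  # double heterozygotes
  # unambiguous haplotype counts contributed by the other eight cells
  base <- c(
    rr = 2 * j[1, 1] + j[1, 2] + j[2, 1],
    ra = 2 * j[1, 3] + j[1, 2] + j[2, 3],
    ar = 2 * j[3, 1] + j[2, 1] + j[3, 2],
    aa = 2 * j[3, 3] + j[3, 2] + j[2, 3])

  ll <- hap_loglik(f, j)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- f["rr"] * f["aa"] + f["ra"] * f["ar"]
    w <- if (denom > 0) f["rr"] * f["aa"] / denom else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll_new <- hap_loglik(f, j)
    if (ll_new < ll - 1e-9)
      warning("EM log-likelihood decreased; numerical trouble")
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations; returning last iterate")
  degenerate <- ndh == n  # every subject double-het: likelihood flat in phase
  stats <- ld_statistics(f)
  structure(
    c(list(hap_freqs = f, em_iterations = it, loglik = ll,
           converged = converged, degenerate = degenerate, n = n), stats),
    class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf(
    "<ld_result> r2 = %.4f  D' = %.4f  D = %.4f  (EM: %d iter%s, n = %d)\n",
    x$r2, x$D_prime, x$D, x$em_iterations,
    if (x$degenerate) ", degenerate" else "", x$n))
  print(round(x$hap_freqs, 4))
  invisible(x)
}

#' LD statistics from haplotype frequencies
#'
#' `D = f_aa - pA * pB` (covariance of alt-allele indicators), `D'` the
#' absolute D normalized by its classical bound given the allele frequencies,
#' and `r2 = D^2 / (pA qA pB qB)`.
#'
#' @param hap_freqs numeric vector of 4 haplotype frequencies in the order
#'   `rr, ra, ar, aa` (first letter = allele at locus 1; `a` = alt), summing
#'   to 1.
#' @return List with `D`, `D_prime`, `r2`.
#' @export
ld_statistics <- function(hap_freqs) {
  f <- unname(hap_freqs)
  if (length(f) != 4 || any(f < -1e-12) || abs(sum(f) - 1) > 1e-6)
    stop("hap_freqs must be 4 non-negative frequencies summing to 1")
  pA <- f[3] + f[4]; pB <- f[2] + f[4]
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined: an allele is fixed")
  D <- f[4] - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       D_prime = if (D == 0) 0 else abs(D) / d_max,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Pairwise LD (r-squared) matrix
#'
#' EM-based r2 for every SNP pair in a group. Pairs where estimation fails
#' (e.g. a monomorphic locus) are reported as `NA` with a message.
#'
#' @param ds a [cohort_dataset()].
#' @param snp_ids at least two rsIDs; defaults to all SNPs in `ds`.
#' @param group `"case"`, `"control"`, or `"pooled"`.
#' @return Symmetric numeric matrix of r2 with unit diagonal.
#' @export
ld_matrix <- function(ds, snp_ids = colnames(ds$geno),
                      group = c("pooled", "case", "control")) {
  group <- match.arg(group)
  if (length(snp_ids) < 2) stop("need at least two SNPs")
  k <- length(snp_ids)
  out <- matrix(NA_real_, k, k, dimnames = list(snp_ids, snp_ids))
  diag(out) <- 1
  for (i in seq_len(k - 1)) for (jj in (i + 1):k) {
    r2 <- tryCatch({
      j <- joint_genotype_counts(ds, snp_ids[i], snp_ids[jj], group)
      em_haplotype_freqs(j)$r2
    }, error = function(e) {
      message("ld_matrix: ", snp_ids[i], " x ", snp_ids[jj], " failed: ",
              conditionMessage(e))
      NA_real_
    })
    out[i, jj] <- out[jj, i] <- r2
  }
  out
}

#' Grayscale LD heatmap
#'
#' Plots an r2 matrix with the conventional encoding: white for r2 = 0,
#' gray shades for intermediate values, black for r2 = 1.
#'
#' @param r2_matrix symmetric r2 matrix from [ld_matrix()].
#' @param main plot title.
#' @return Invisibly, the matrix.
#' @export
plot_ld_matrix <- function(r2_matrix, main = "Pairwise LD (r2)") {
  k <- ncol(r2_matrix)
  graphics::image(seq_len(k), seq_len(k), t(r2_matrix[k:1, , drop = FALSE]),
                  zlim = c(0, 1),
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(k), colnames(r2_matrix), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(rownames(r2_matrix)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(r2_matrix)
}
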