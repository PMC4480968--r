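---
title: "Candidate-gene case-control analysis of kidney stone disease with stonekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene case-control analysis of kidney stone disease with stonekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonekit)
```

## The scientific setting

Calcium kidney stone disease is a multifactorial disorder in which altered
renal calcium handling — hypercalciuria above all — is the dominant
intermediate phenotype. Three genes sit squarely in that pathway: *CaSR*
(the calcium-sensing receptor governing PTH release and tubular calcium
reabsorption), *VDR* (the vitamin D receptor regulating calcium absorption
and, indirectly, *CaSR* expression) and *CLDN14* (a tight-junction claudin
controlling paracellular calcium permeability in the thick ascending limb).

stonekit implements the complete statistical machinery of a candidate-gene
case-control study of these genes: eight biallelic SNPs typed in 200 stone
formers and 200 age- and sex-matched controls, with genotype coded as the
count of variant alleles (0/1/2). The individual-level data behind the
original study were never deposited; what is public are the per-SNP
genotype count tables, group-level trait summaries, and carrier-stratified
trait summaries. The package therefore carries two complementary objects:

* `ksd_counts()` — the printed genotype count tables themselves, the ground
  truth for every count-based statistic; and
* `ksd_cohort(seed)` — a synthetic 400-subject cohort whose per-SNP counts
  equal those tables *exactly* (see "Synthetic cohorts" below), for
  exercising the subject-level stages (regression adjustment, LD, risk
  scores, trait tests).

## Association statistics

For each SNP, four genetic models reduce the genotype counts to 2×2 tables:
allelic (variant vs reference allele counts), genotypic (het vs homRef and
homAlt vs homRef), dominant (carriers vs homRef) and recessive (homAlt vs
the rest). Each table yields the odds ratio $\hat{OR} = ad/bc$ with the
Woolf confidence interval

$$\exp\left(\ln \hat{OR} \pm z_{1-\alpha/2}
  \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),$$

which reproduces every count-consistent interval printed for the reference
cohort, including extreme ones such as 22.67 (2.94–174.82) for the
rs1042636 GG homozygote contrast. Design choices worth stating:

* **Chi-square without Yates continuity correction.** The reference
  significance calls only reproduce without the correction, which is also
  the convention of the association software this field typically uses.
* **Fisher exact when any expected cell is below 5** (the classic rule),
  computed by summing hypergeometric probabilities no larger than the
  observed table's. For larger tables the Pearson chi-square (1 df) is used.
* **Haldane–Anscombe +0.5** applied only when exactly one cell is zero.
  None of the reference tables needs it; contrasts whose exposed genotype
  class is empty everywhere (the rs1801726 GG class) are omitted with a
  message rather than faked.
* **Bonferroni with m = 8** by default — one test per SNP discovered — and
  overridable, since the source analysis never states its m.

`hwe_chi2()` compares observed genotype counts with Hardy–Weinberg
expectations at the observed allele frequency (1 df). We compute it in
cases and controls separately; the conventional quality-control reading
uses the controls. On the reference counts the rs731236 controls fail
spectacularly (χ² ≈ 34.9) while rs1801725 controls pass — but note that the
1-df chi-square also flags rs1042636 controls (p ≈ 0.01) purely on the
strength of one observed GG homozygote against 6.3 expected; with expected
counts that small the chi-square is anticonservative and an exact HWE test
would be the cautious follow-up.

```{r assoc}
sweep <- suppressMessages(association_sweep(ksd_counts(), ksd_snps()))
subset(sweep, model == "allelic",
       select = c(snp_id, contrast, or, ci_low, ci_high, p_bonferroni))
```

### Known inconsistencies in the reference tables

The golden tests pin every printed OR/CI that is arithmetically consistent
with the genotype counts. Four printed values are not, and are excluded:
the rs219777 allelic OR (printed 1.90, counts give 1.71), the rs2228570 and
rs731236 allelic ORs (1.25 vs 1.19, 0.94 vs 0.90), and the whole rs731236
genotype-row block, whose printed values duplicate the rs219777 rows. The
rs731236 and rs219778-case allele frequencies likewise disagree with the
counts beyond printing precision. The count tables are treated as ground
truth throughout.

## Linkage disequilibrium from unphased genotypes

With unphased genotypes, only the double heterozygote is phase-ambiguous.
`em_haplotype_freqs()` runs the standard two-locus EM: initialize at
linkage equilibrium of the observed allele frequencies, split the double
heterozygotes between the two phase resolutions in proportion to
$f_{rr}f_{aa} / (f_{rr}f_{aa} + f_{ra}f_{ar})$, re-estimate, and stop when
no frequency moves by more than `tol` (default 1e-8, capped at 1000
iterations — a warning, not an error, on hitting the cap). The
log-likelihood is non-decreasing by construction and the estimate conserves
the observed allele margins exactly, which leaves a single free parameter;
the test suite exploits that by checking the EM against a brute-force grid
maximization over $f_{aa}$. A sample consisting *only* of double
heterozygotes has a likelihood flat in phase; the estimator then stays at
the equilibrium initializer and sets a `degenerate` flag instead of
pretending to know the phase.

From the haplotype frequencies, $D = f_{aa} - p_A p_B$,
$D' = |D|/D_{\max}$ with the classical frequency-dependent bound, and
$r^2 = D^2/(p_A q_A p_B q_B)$. `ld_matrix()` assembles pairwise $r^2$ per
group (cases and controls separately, mirroring the two-panel LD figure
convention; pooled on request), and `plot_ld_matrix()` renders the
white–gray–black encoding. Because the synthetic cohort assigns SNPs
independently (the joint genotypes were never published), its LD is null by
construction — which matches the original report of no LD among the
*CaSR* or *CLDN14* SNPs, but is a modelling assumption, not a finding.

## Covariate adjustment

`adjusted_or()` fits case status on a binary genotype exposure plus
covariates by logistic regression (IRLS via `glm`, tight convergence
epsilon), returning the exponentiated exposure coefficient with a Wald
interval. Sex is coded 0/1 (female/male); age and BMI enter untransformed —
the original covariate coding is unstated, and with individual-level
covariates unpublished the printed adjusted ORs are *not* reproducible;
they are deliberately not test targets. What is testable is structure: with
no covariates the fit collapses to the crude OR (to 1e-6); the estimate is
invariant to affine covariate rescaling; a known exposure log-odds of 0.8
is recovered with near-nominal Wald coverage on simulated cohorts of
n = 2000; and separation is flagged (`converged = FALSE`) rather than
reported as a huge finite OR. Each contrast is fit as its own binary model
(het and homAlt contrasts restrict to the two genotype classes involved),
matching how the per-row adjusted ORs are laid out.

## Multi-locus risk: carriers and the dosage score

`combined_carrier_or()` compares disease odds between disjoint strata
defined by the number of loci at which a subject carries at least one risk
allele (both/one/none, or arbitrary count sets), excluding subjects with
any missing genotype in the set — the same complete-genotype rule the
original combined analyses used.

The weighted allele dosage score addresses non-uniform effect sizes across
the k loci. With $R_i \in \{0,1,2\}$ risk alleles and weights
$W_i = \log OR_i$:

$$\text{score} = \frac{\sum_i W_i (R_i/2)}{\sum_i W_i} \in [0,1], \qquad
  \text{effective alleles} = 2k \cdot \text{score}
  = \frac{k\sum_i W_i R_i}{\sum_i W_i} \in [0, 2k].$$

The score is the weighted mean of the per-locus risk-allele *proportion*;
multiplying by 2k expresses it on the scale of a plain allele count, so a
subject homozygous for every risk allele scores 2k (8 for the default
k = 4) and equal weights reduce it to the unweighted count. Weights enter
only as ratios, so the logarithm base is immaterial (property-tested). The
default weights are the crude allelic ORs of the four associated SNPs
(2.54, 2.21, 3.01, 2.19), recomputed from the count tables at run time;
whether the original analysis used crude, dominant or adjusted ORs is
unstated, so the weight set is a constructor argument.

`dosage_category_analysis()` bins effective-allele counts at boundaries
`c(2, 3, 4)` into ≤2 (reference), (2,3], (3,4] and >4, right-closed. The
source material describes the reference as both "less than 2" and "two or
fewer"; we resolve toward "two or fewer" and make the boundaries
configurable. Category ORs are computed against the reference with the same
chi-square/Fisher routing as everywhere else.

```{r dosage}
ds <- ksd_cohort(seed = 1)
dosage_category_analysis(ds, ksd_dosage_weights())
```

The published joint-genotype results (combined-carrier ORs 2.02, 5.09,
9.50, 8.29, the 27.5-fold top-category OR and the 5% / 76.5% category
fractions) depend on the unpublished joint distribution of genotypes across
loci and are therefore not reproduction targets: the procedures are instead
validated by parameter recovery on synthetic cohorts generated with known
per-stratum odds.

## Quantitative traits

`t_test_summary()` implements the pooled-variance Student t-test (Welch
optional) directly from means, SDs and group sizes — necessary because
several reference comparisons exist only as summary statistics. It
reproduces the published serum-calcium comparison of 4-risk-allele carriers
(9.73 ± 0.21, n = 9) vs the rest (9.46 ± 0.28, n = 282): t ≈ 2.87 on 289
df, p ≈ 0.0045, printed as 0.005. The statistic is positive when the second
group's mean is larger, and the summary form agrees with the raw-data
t-test to 1e-9 (tested).

`mann_whitney_u()` uses exact enumeration over all $\binom{n}{n_1}$ rank
assignments when $n_1 + n_2 \le 16$ (valid under ties via midranks;
two-sided p counts assignments at least as far from the null mean of U) and
the tie-corrected normal approximation above that. The threshold is a
compute/accuracy trade-off: enumeration at 16 is ~13k assignments.
`trait_by_genotype()` wires either test to genotype strata (dominant,
recessive, het-vs-homRef) within cases, controls or the full cohort.

## Synthetic cohorts

`generate_cohort()` supports two genotype regimes per SNP:

* **Exact-count mode** — the genotype multiset implied by the target counts
  is permuted within each group. Per-SNP counts match the spec *exactly*,
  so every count-based statistic is seed-invariant; only the assignment of
  genotypes to subject IDs varies with the seed.
* **Frequency mode** — Hardy–Weinberg sampling at the given alt-allele
  frequency; optional pairwise r² targets are honoured by drawing two
  haplotypes per subject at the haplotype frequencies implying the target
  (positive-D convention), with an error stating the feasible maximum when
  the target exceeds the frequency-determined bound.

`ksd_cohort()` is the exact-count instantiation of the reference study:
200/200 subjects, all eight SNP count tables pinned, age/sex/BMI and the
urine/serum biochemistry drawn from the published group means ± SDs, and
serum calcium / urinary calcium drawn per rs1801725 / rs1042636 carrier
stratum from the carrier-stratified summaries (group-level models are the
fallback precedence for subjects outside a stratified table). Traits are
independent normals within strata — measurement error models, trait
correlations and the joint genotype distribution are *not* emulated, so
passing tests on this cohort demonstrate the pipeline's correctness on data
with the published marginal structure, not re-findings about the original
patients.

## Orchestration and output conventions

`run_full_analysis()` chains the stages on one dataset and writes one TSV
per stage (allelic and genotype-model association, HWE, LD, adjusted ORs,
dosage categories, trait comparisons) plus a JSON summary and a run log;
outputs are deterministic given dataset and seed, a failing stage removes
partial output and names itself, and an invalid configuration aborts before
any computation. Display formatting follows the reference conventions —
ORs/CIs to 2 decimals, p-values to 3 with a "<0.001" floor — but only in
display columns; full precision is kept in every numeric column. The
package's entry points are ordinary R functions; the reproduction script
`scripts/acceptance.R` is the command-line wrapper over them.

Problem sizes used by the test suite (simulation-based checks): parameter
recovery for the logistic adjustment at n = 2000 × 100 replicates; crude-OR
recovery in frequency mode at n = 40,000; combined-carrier recovery at
n = 2000–4000; EM-vs-grid checks at n = 100 subjects per table. These sizes
make Monte-Carlo noise small relative to the asserted tolerances.

## Known limitations

* Cross-SNP independence in the synthetic cohort (see above) — multi-locus
  results on it are procedure checks, not value reproductions.
* The chi-square HWE test is anticonservative at small expected homozygote
  counts; an exact HWE test is not implemented.
* No Cochran–Armitage trend test, haplotype association, haplotype blocks,
  or matched-pair (conditional) regression — the reference analysis used
  none of them.
* The adjusted-OR stage cannot be validated against the printed adjusted
  ORs (covariates unpublished); validation is structural and simulation
  based.
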