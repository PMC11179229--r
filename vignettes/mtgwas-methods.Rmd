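---
title: "Methods: multi-trait mixed-model GWAS with factor-analytic trait covariance"
author: "mtgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgwas)
```

This vignette is the package's account of its statistical machinery:
the models, the estimators, the numerical choices, and the synthetic
data that the test suite exercises them on. It states no empirical
result that the tests and `scripts/acceptance.R` do not themselves
compute.

## 1. Stage 1: trial models, BLUEs and generalized heritability

Plot-level data from three designed-experiment layouts are supported,
each with its conventional mixed model:

* **lattice** — replicate fixed, incomplete block random within
  replicate, check entries fixed, line random or fixed;
* **RCBD** — block (= replicate) fixed, line random or fixed;
* **augmented** — block random, checks fixed (replicated in every
  block), test lines unreplicated, random or fixed.

The line effect is fitted *random* to estimate the genetic variance
$\sigma^2_g$ by REML and to produce BLUPs, then *fixed* to produce the
adjusted means (BLUEs) that enter the association stage. Right-skewed
3D architecture traits (convex-hull volume, median root counts) can be
natural-log transformed before fitting (`transform = "log"`).

REML estimation is delegated to `lme4` — these are entirely standard
variance-component fits. What `lme4` does not expose is the full
prediction-error-variance (PEV) matrix of the line BLUPs, which the
Cullis heritability needs, so `fit_trial()` rebuilds the mixed-model
equations at the REML estimates and inverts the coefficient matrix
(dense; a few hundred equations at panel scale). Check entries are
excluded from the random line term by giving each line a slope on a
0/1 test-line indicator, so checks contribute only fixed effects, as
the models specify.

The generalized heritability is
$H^2 = 1 - \bar v_{\mathrm{BLUP}} / (2\hat\sigma^2_g)$, with
$\bar v_{\mathrm{BLUP}}$ the mean over all line pairs of
$\mathrm{PEV}_{ii} + \mathrm{PEV}_{jj} - 2\,\mathrm{PEV}_{ij}$,
computed exactly (the $n^2$ pair sum is cheap below a few thousand
lines). $H^2$ is clipped to $[0,1]$ and defined as 0 when
$\hat\sigma^2_g = 0$. On a balanced RCBD this reduces analytically to
the entry-mean heritability $\sigma^2_g / (\sigma^2_g + \sigma^2_e/r)$,
which the suite verifies to $10^{-6}$.

BLUEs are standardized per trait to zero mean and unit sample variance
($n-1$ denominator) over observed entries; lines not scored for a
trait stay missing. Standardization happens after the per-trait
stage-1 fits, trait by trait.

## 2. Stage 2: the Kronecker null model

For $n$ lines and $T$ traits the no-marker model is
$y_{it} = \mu_t + G_{it} + \epsilon_{it}$ with
$$\mathrm{vec}(Y^\top) \sim N\!\big((X \otimes I_T)\beta,\;
K \otimes \Sigma_T + I_n \otimes \Sigma_R\big),$$
where $K$ is the VanRaden genomic relationship matrix
($W W^\top / 2\sum_j p_j(1-p_j)$, allele frequencies computed from the
imputed calls; expected diagonal 2 on a fully inbred panel),
$\Sigma_T$ is the between-trait genetic covariance, and $\Sigma_R$ is
diagonal — no residual covariance between traits, because each trait's
residual comes from its own experiment.

Three parameterizations of $\Sigma_T$ are fitted and compared by AIC:

| structure | form | parameters (with $\Sigma_R$) |
|---|---|---|
| FA1 | $\lambda\lambda^\top + \mathrm{diag}(\psi)$ | $3T$ |
| FA2 | $\Lambda\Lambda^\top + \mathrm{diag}(\psi)$, $\Lambda_{1,2}=0$ | $4T-1$ |
| UNS | $LL^\top$ (Cholesky) | $T(T+1)/2 + T$ |

The FA2 identifiability constraint $\Lambda_{1,2}=0$ pins the rotation
freedom of the two-factor loadings; any other rotation convention gives
the same covariance and likelihood. Specific variances, residual
variances and Cholesky diagonals live on the log scale, which keeps
every candidate covariance positive (semi)definite by construction.
AIC is $-2\ell_R + 2k$ counting covariance parameters only; all
candidates share the same fixed effects, so REML likelihoods are
comparable. Ties go to the structure with fewer parameters.

### Likelihood evaluation

With complete trait data the likelihood is evaluated exactly in
$O(nT)$ per iteration: decompose $K = U D U^\top$ once, rotate
$\tilde Y = U^\top Y$, and simultaneously diagonalize the trait pair
($Q^\top \Sigma_R Q = I$, $Q^\top \Sigma_T Q = \mathrm{diag}(\lambda)$,
with $Q = \Sigma_R^{-1/2} P$ from a $T \times T$ symmetric
eigenproblem). Every rotated observation row then has diagonal
covariance $d_i\lambda_t + 1$ and the restricted likelihood decomposes
into $T$ independent weighted regressions. The REML score is computed
analytically in the same basis — every derivative reduces to
contractions of a handful of $T \times T$ matrices accumulated over
rows — so a gradient costs about one likelihood evaluation; the suite
checks the analytic score against central finite differences.
Optimization uses `nlminb` (relative tolerance $10^{-10}$, up to 500
iterations). Starting values: $\Sigma_R = \tfrac12$ the per-trait
sample variance, $\Sigma_T$ = half the sample covariance projected
onto each family by eigen-truncation. To keep the nested families
consistent, FA2 is additionally started from the FA1 solution and UNS
from the best factor-analytic solution; each structure keeps its best
converged start, and the suite asserts
$\ell(\mathrm{UNS}) \ge \ell(\mathrm{FA2}) \ge \ell(\mathrm{FA1})$
within $10^{-4}$.

With missing trait cells the fit falls back to the exact restricted
likelihood of the observed cells of the dense $(nT)\times(nT)$
covariance (Cholesky-based, numeric gradient). This is cubic in the
number of observed cells and intended for panel scale (hundreds of
lines), not genome scale; it is exact rather than an EM completion.
Both paths are verified against an independently coded dense oracle to
$10^{-8}$.

## 3. The scan, thresholds, and refits

**Scan (step 2).** For each SNP, per-trait effects $\alpha_t$ and
intercepts are estimated by GLS under the *frozen* null covariance,
with $K$ replaced by the leave-one-chromosome-out kinship $K_c$ of the
SNP's chromosome — excluding the tested chromosome keeps the polygenic
correction from absorbing the very signal being tested. The inverse
covariance machinery (eigendecomposition of $K_c$, simultaneous
diagonalization) is computed once per chromosome and reused across its
SNPs; the per-SNP work is a set of $2\times 2$ weighted regressions,
vectorized across SNPs. The joint Wald statistic
$\hat\alpha^\top \mathrm{Var}(\hat\alpha)^{-1}\hat\alpha$ is referred
to $\chi^2_T$ — trait-specific marker effects give $T$ degrees of
freedom; this reference distribution is a package choice and is
validated by simulation (Section 5). Monomorphic SNPs and SNPs with a
singular effect covariance are skipped and logged. The scan expects
imputed calls (the pipeline imputes by SNP mode first).

**Thresholds.** The number of independent tests is taken as genome
length over average LD extent; the significance threshold is
$-\log_{10}(\alpha / (L/\ell))$. The shipped default genome length is
659.2 Mb (the ten-chromosome sorghum v2.1 total — configure it for any
other genome); with $\alpha = 0.05$ and $\ell = 150$ kb this prints as
4.94. Suggestive associations sit in $[4.0, 4.94)$; a SNP exactly at
the significance threshold is significant ($\ge$ rule).

**Refit (step 3).** Each significant or suggestive SNP is re-fitted
one at a time under full REML with the SNP as a trait-specific fixed
effect and the full-genome kinship, so all variance components are
re-estimated conditional on the fitted SNP. Reported per trait:
effect, standard error, normal-approximation 95% CI
($\pm 1.96\,\mathrm{SE}$), Wald p ($\chi^2_1$), favorable allele
(minor when $\hat\alpha > 0$ under the 0/2 minor-dosage coding), and
variance explained $100\,\hat\alpha^2\,4p(1-p)/V_{p,\mathrm{null}}$,
where $4p(1-p)$ is the genotype-code variance on an inbred panel and
$V_{p,\mathrm{null}}$ is the per-trait phenotypic variance of the
*null* model ($\mathrm{diag}(\Sigma_T) + \Sigma_R$ from step 1, not
assumed to be exactly 1 after standardization). If the refit fails to
converge the step-2 GLS estimates are returned with a warning flag.

**LD.** $r^2$ is the squared Pearson correlation of the 0/2 codes over
pairwise-complete lines (on an inbred panel the genotype table *is*
the haplotype table); significance is a two-sided Fisher exact test on
the $2\times2$ homozygote-class table. Neighborhoods pair each
associated SNP with everything within a closed 2,000-kb window on its
chromosome, plus all associated-associated pairs sharing a chromosome.

## 4. The synthetic panel generator

The generator emulates the features of a sorghum-like association
panel that the pipeline is sensitive to, at desk scale. Defaults: 272
inbred lines, 10 chromosomes of 65.92 Mb (so the simulated genome
totals the 659.2 Mb behind the default threshold), 250 pre-filter SNPs
per chromosome, LD extent 150 kb, eight traits whose default genetic
covariance has a two-factor structure with mostly positive loadings,
and the three trial designs (lattice with 3 replicates and 9 incomplete
blocks and two checks; RCBD with 3 replicates; augmented with 14 blocks
and 2 checks per block).

Genotypes come from a **two-layer founder mosaic**: two complementary
deep haplotypes differ at every site; each of 16 founders is a
segment-wise mosaic of the two with a founder-specific mixture weight
drawn from $U(0.05, 0.95)$ (this spreads the allele-frequency
spectrum); each line is a segment-wise mosaic of the founder pool,
drawn with skewed per-chromosome usage weights (normalized
$\mathrm{Gamma}(0.4)$ — few locally common haplotypes, as in a
diversity panel). All segment lengths are exponential. A single-layer
mosaic over independent founder haplotypes cannot produce strong
short-range LD — panel-level $r^2$ is then bounded by founder-level
noise $\approx 1/(n_f-1)$ — which is why the founders are themselves
mosaics. Allele correlation at distance $d$ requires both the
line-level and the founder-level segment to survive, and $r^2$ is the
squared correlation, so the internal segment mean is set to
$3\times$ `ld_segment_bp`; with that calibration the fitted decay
length of the mean-$r^2$ curve matches the parameter to within
sampling error (the suite checks $\pm 30\%$). Genetic values are
$X_{\mathrm{QTL}}A + U$ with $U$ matrix-normal (row covariance = the
panel kinship scaled to unit mean diagonal, column covariance =
$\Sigma_T^{\mathrm{true}}$), columns centered. Trial simulation adds
replicate/block/error draws around the line values and honors a
missing-plot rate. One integer seed drives everything; fixed seed,
identical output.

What the generator does **not** emulate: the rare-allele-heavy MAF
spectrum of GBS panels (its spectrum is common-allele-shifted; the
panel-characterization filters still apply meaningfully), explicit
subpopulation structure (relatedness arises only from founder sharing),
selection, epistasis, and sequence-level artifacts. Passing tests
therefore show correctness of the estimators under a realistic LD and
relatedness regime, not robustness to strong stratification.

## 5. Reference study conditions and validation design

The acceptance-level tests run at fixed, documented problem sizes:

* **Dense-oracle equivalence** at $n \le 8$, $T \le 3$, tolerance
  $10^{-8}$ (likelihood) and $10^{-10}$ (GLS effects).
* **Type-I calibration**: 300 lines, 10 × 200 SNPs, 4 traits, FA2-truth
  $\Sigma_T$. Because the scan conditions on the LOCO kinship, the
  matched null draws the polygenic background from that same
  leave-one-chromosome-out matrix, chromosome by chromosome; duplicate
  SNP columns are dropped before the Kolmogorov–Smirnov test (identical
  markers repeat the same test). Drawing the background from the
  full-genome kinship instead leaves the own-chromosome polygenic share
  unmodeled and visibly inflates the scan ($\lambda \approx 1.2$ at
  these sizes) — that is the known, deliberate trade-off of LOCO
  correction, not a defect of the GLS test, and the calibration test
  separates the two.
* **Covariance recovery**: unstructured $\Sigma_T$ ($T=3$, diagonal 1,
  off-diagonals 0.5/0.2/0.4), $\sigma^2_R = 0.3$, $n = 500$ on a
  10-chromosome, 32-founder panel, 100 replicates — conditions chosen
  so the kinship supplies adequate effective replication. Fitted
  $\Sigma_T$ is compared on the kinship scale (mean diagonal 2 absorbs
  a factor of ½).
* **Structure selection**: FA2 truth with loadings
  $(0.9..0.4)$ / $(0, 0.6, -0.5, 0.5, -0.4, 0.3)$, $\psi = 0.2$,
  $T = 6$, $n = 400$, 100 replicates.
* **Power**: a pleiotropic SNP with effects $(0.25, 0.25, 0, 0)$ on 4
  correlated traits, $n = 400$, 200 replicates; the scan in this
  replicated comparison conditions on the generating covariance (the
  GLS scan is defined conditional on a supplied covariance; this keeps
  joint and single-trait tests on identical footing).
* **End-to-end**: 200 lines, 10 × 200 SNPs, 4 traits, three planted
  pleiotropic QTLs (effects 0.35–0.45 on 2–4 traits), 10 seeds; a QTL
  counts as recovered when a significant SNP lies within 250 kb, and
  stray significant SNPs are clustered into 250-kb regions before
  counting false positives.

## 6. Numerical choices and degenerate inputs

* MAF thresholds are strict removals (`maf < threshold` removed; a SNP
  at the threshold is kept); missing-rate removal is `> 0.20`.
  All-missing SNPs are flagged and removable; imputation refuses them.
* Mode imputation ties break to the major-allele homozygote. The minor
  allele is defined per SNP in the analyzed panel after filtering; at
  exactly $p = 0.5$ the existing (ALT/second-listed) orientation is
  kept.
* Allele frequencies for kinship centering and the denominator are
  computed after imputation.
* Eigenvalues of $K$ are clipped at 0; kinship must be PSD to $-10^{-6}$.
* Variance floors: $10^{-6}$-scale ridges on Cholesky starts;
  variances bounded below via the log parameterization.
* $H^2$ clipped to $[0,1]$; $\sigma^2_g = 0 \Rightarrow H^2 = 0$.
* Confounded stage-1 designs (every block holding a single unreplicated
  line) are refused with a diagnostic rather than silently fitted.
* VCF input rejects heterozygous calls by default (`het = "missing"`
  masks them instead); multi-allelic records are refused.
* Positions are 1-based bp; chromosome labels are strings.

## 7. Known limitations

* The missing-cell REML path is exact but cubic in observed cells;
  beyond a few thousand cells it is slow. The scan's missing-data path
  is likewise dense per chromosome.
* No population-structure fixed covariates (principal components):
  correction is through kinship only, by design. Strongly stratified
  panels may need more.
* Step-3 refits are single-SNP; no multi-locus or Bayesian modeling.
* The paper-scale data (hundreds of thousands of SNPs, real
  phenotypes) are not shipped; all empirical statements in the test
  suite are about the synthetic reference studies described above.
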