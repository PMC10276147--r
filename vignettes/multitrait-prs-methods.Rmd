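---
title: "Sparse multi-trait polygenic scores from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-trait polygenic scores from summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvlassosum)
```

## The problem

A polygenic risk score (PRS) predicts a trait or disease liability as a
weighted sum of allele counts. When two disorders are genetically correlated
— schizophrenia and bipolar disorder are the motivating pair — borrowing
strength across their genome-wide association studies (GWAS) improves each
trait's score. `mvlassosum` builds sparse PRSs for $q \ge 2$ correlated
traits jointly, using only GWAS summary statistics, a reference genotype
panel for linkage disequilibrium (LD), and optionally per-SNP genomic
annotations.

## Model

For standardized genotypes $x_{ij}$ and centered traits, SNP $j$'s effects
across traits are correlated random effects
$\beta_j = (\beta_{j1},\dots,\beta_{jq}) \sim N(0, \Sigma_{bj})$, with
diagonal residual covariance $\Sigma_s = \mathrm{diag}(1 - h^2_{g1}, \dots,
1 - h^2_{gq})$ when all trait variances are set to 1. Adding a weighted
LASSO penalty to the joint log-density of the data and the random effects,
and replacing individual-level quantities by the SNP-trait correlations
$r_{jk}$ (recoverable from published association statistics via
$r = t/\sqrt{n - 2 + t^2}$) and a reference-panel LD matrix $R$, gives the
objective

$$
f(\beta) = \sum_j \beta_j^\top \Sigma_{bj}^{-1} \beta_j
 - 2\sum_j \beta_j^\top \Sigma_s^{-1}\,\mathrm{diag}(n)\, r_j
 + \sum_{j,l} \beta_j^\top \mathrm{diag}(n)\big(\tilde X_j^\top \tilde X_l
   + s\,\mathbb{1}_{j=l}\big)\Sigma_s^{-1} \beta_l
 + 2\lambda \lVert W\beta \rVert_1,
$$

up to a constant, where $\tilde X = \sqrt{(1-s)/n_r}\,X_r$ and
$R_s = (1-s)R + sI$ regularizes the LD matrix. The penalty weights $W$ are
all ones (plain LASSO) or $w_{jk} = |\hat\beta_{jk}|^{-\gamma}$ (adaptive
LASSO from GWAS effects, or from a first constant-penalty fit with
$\gamma = 1$).

Coordinate descent minimizes $f$ one coefficient at a time:
$\beta_{jk} \leftarrow \mathrm{soft}(A_{jk}, \lambda w_{jk}) / D_{jk}$ with
curvature $D_{jk} = n_k(\tilde X_j^\top \tilde X_j + s)/\sigma^2_{\epsilon k}
+ (\Sigma_{bj}^{-1})_{kk}$. The numerator $A_{jk}$ collects the data term,
the LD term over the SNP's block, and the cross-trait coupling
$-c\sum_{h \ne k} (\Sigma_{bj}^{-1})_{kh}\beta_{jh}$.

**Cross-term factor.** Differentiating the objective gives $c = 1$ on the
cross-trait coupling, while the update rule has also circulated with
$c = 1/2$. Both variants are implemented (`cross_term_factor`); the default
is the gradient-consistent $c = 1$, because only that variant minimizes the
stated objective — the package's convex-oracle tests check each variant
against the quadratic form its own updates minimize, and only $c = 1$
matches the objective above. The $c = 1/2$ fixed point minimizes the same
objective with the prior form replaced by
$\mathrm{diag}(P) + \tfrac12(P - \mathrm{diag}(P))$, $P = \Sigma_{bj}^{-1}$,
which is also convex, so both variants are valid descent methods — they just
target different priors.

## Solver mechanics and numerical choices

* **Block-diagonal LD.** LD is computed per block (an interval file, or a
  fixed window of 500 SNPs by default); cross-block LD is zero by
  construction, the convention of summary-statistic LASSO methods. The
  regularized operator $(1-s)\hat R_l + sI$ is positive definite for any
  $s \in (0,1]$; $s = 0.5$ is the default, with 0.2/0.9/1 used for
  sensitivity analyses.
* **Standardization.** Genotypes are standardized by $\sqrt{2\hat p(1-\hat
  p)}$ with the empirical allele frequency, so standardized columns have
  exact zero mean but only approximately unit variance; the solver uses the
  actual diagonal $\tilde X_j^\top \tilde X_j$ rather than assuming 1.
* **Sweeps.** SNP-major order (all traits within a SNP before moving on),
  so the cross-trait coupling always uses the freshest coefficients. After
  the first full sweep per penalty, only the active set is cycled; a final
  full sweep confirms convergence (standard elastic-net practice — same
  fixed point, large speedup).
* **Convergence.** Maximum absolute coefficient change below `tol` (default
  `1e-4` on the standardized scale), at most `maxit = 100` sweeps per
  penalty value, warm starts along the descending path. The objective is
  recorded each sweep and is non-increasing by construction (exact
  coordinate minimization of a convex function); `kkt_check()` provides an
  optimality certificate after the fact.
* **Caching.** The solver maintains $\hat R \beta$ per block with rank-one
  column updates; the cache is returned and tested to equal direct
  computation to $10^{-10}$.
* **Infinite weights** (from an adaptive source coefficient of zero) pin
  coefficients at zero via a skip, not arithmetic on infinities.
* **Degenerate $\Sigma_{bj}$.** Before inversion, matrices whose smallest
  eigenvalue is (near) zero get an epsilon floor of $10^{-3} h^2_{gk}/p$
  per trait on the diagonal; SNPs with no genetic contribution at all
  therefore get a heavily ridge-penalized (not undefined) coefficient.

## Tuning with pseudo summary statistics

Without individual-level validation data, the full-sample correlations are
split into pseudo training and validation parts:
$r_{Ak} = r_k + \sqrt{n_B/(n_{Ak} n_k)}\; s(r_k)\; X_r^\top g / \sqrt{n_r}$
with $g \sim N(0, I_{n_r})$, and $r_{Bk} = (n_k r_k - n_{Ak} r_{Ak})/n_B$,
so that $n_{Ak} r_{Ak} + n_B r_{Bk} = n_k r_k$ holds identically. The
validation size $n_B$ is 10% of the mean GWAS sample size. The printed form
of the perturbation scale is ambiguous in its source; the implementation
uses the unique scaling under which the training and validation parts have
the sampling covariances of correlation estimates from $n_{Ak}$ and $n_B$
subjects, namely $(n_B/(n_{Ak} n_k))\, s^2(r_k)\, \hat R$ — verified by a
Monte-Carlo moment test. Whether the perturbation vector $g$ is shared
across traits is also unstated; the default shares one $g$ (preserving
cross-trait noise structure), with `shared_g = FALSE` available.

The penalty is chosen to maximize

$$
f(\lambda) = \frac{\beta_\lambda^\top r_B}
{\sqrt{\tfrac{1}{n_0} \beta_\lambda^\top X_0^\top X_0 \beta_\lambda}},
$$

a summary-statistic surrogate for the correlation between the PRS and the
trait in a validation sample. For $q > 1$ the stacked (single-ratio) form is
used as written, with per-trait ratios emitted as diagnostics so the choice
is auditable. The all-zero solution is excluded via a $-\infty$ sentinel.
Penalty grids are log-spaced from $\lambda_{\max}$ (the smallest value with
an all-zero solution, computed in closed form from the zero-coefficient
numerator) and extended downward until at least 5% of SNPs are nonzero per
trait. Ties in the argmax go to the largest penalty (sparsest model), then
to the first model in list order. Pseudovalidation via shrunken
correlations is deliberately not implemented.

## Genetic covariance models

Two specifications of the per-SNP matrices $\Sigma_{bj}$ are provided:

* **Constant:** $\Sigma_{bj} = \Sigma_b / p$ for all SNPs, e.g.
  $\Sigma_b = \begin{pmatrix} 0.47 & 0.27 \\ 0.27 & 0.45 \end{pmatrix}$
  for the schizophrenia/bipolar reference setting.
* **Annotation-based:** cross-trait stratified LD-score regression
  estimates the effect $\theta_C$ of each annotation on the genetic
  covariance from $E[Z_{j1} Z_{j2}] = \sqrt{n_1 n_2} \sum_C \ell(j, C)
  \theta_C + b_{12}$, with $\ell(j,C) = \sum_l a_{lC} R^2_{jl}$, and the
  effects $\tau_{kC}$ on heritabilities from the companion single-trait
  form $E[Z^2_{jk}] = 1 + n_k \sum_C \ell(j,C)\tau_{kC}$. The intercept
  $b_{12}$ (absorbing sample-overlap noise; the overlap correlation is
  $b_{12}/\sqrt{b_1 b_2}$) is fixed at 0 unless requested; note it enters
  unscaled, which is what makes an estimated $b_{12}$ of about 0.18
  translate into an overlap correlation of about 0.16. Regression weights
  default to unweighted least squares with an optional
  $1/\ell(j,\mathrm{baseline})$ choice; block-jackknife standard errors are
  out of scope (large-sample LS standard errors are reported instead).

Per-SNP predictions $\hat h^2_{gk}(j) = \sum_C a_{jC}\hat\tau_{kC}$ and
$\hat\rho_g(j) = \sum_C a_{jC}\hat\theta_C$ can be negative or violate
positive semidefiniteness, so `repair_and_scale()` floors heritabilities at
0 and replaces covariances exceeding $\sqrt{h^2_1(j) h^2_2(j)}$ by
$\max(0, \sqrt{h^2_1(j) h^2_2(j)} - 0.001)$. The repair formula returns a
non-negative magnitude; by default the predicted sign is retained
(preserving negative local covariance while guaranteeing PSD), with the
literal non-negative variant available as `sign_policy = "nonnegative"`.
Matrices are then rescaled so per-trait totals match target heritabilities;
the covariance scale is the geometric mean $\sqrt{c_1 c_2}$ of the two
trait factors, chosen because it leaves every SNP's
covariance-to-heritability ratio unchanged.

## What the simulator emulates

The generator reproduces the study conditions of a two-trait
(schizophrenia/bipolar-like) simulation design:

* heritabilities $(0.47, 0.45)$ (high) or $(0.10, 0.09)$ (low);
* polygenicity: proportions of SNPs influencing traits 1 and 2 of
  $(0.49, 0.47)$ with $P(\text{both}) = 0.35$ (high), or $(0.12, 0.10)$
  with $P(\text{both}) = 0.08$ (low), assigned i.i.d. multinomially;
* genetic correlation 0.59 (high) or 0.44 (moderate) under the
  four-covariance-matrix mixture;
* GWAS sample sizes 23,330 per trait with 3,000-subject reference and test
  panels;
* trait prevalences 1% and 2% under a liability threshold model
  $L = G + E$, $\mathrm{Var}(E) = 1 - h^2_g$, threshold
  $\Phi^{-1}(1 - K)$ on the theoretical unit-variance liability (an
  empirical-quantile option exists);
* optional sample overlap giving cross-trait summary-statistic noise
  correlation 0.16 or 0.32.

Summary statistics are sampled region-wise:
$r_{lk} \sim N(\hat R_l \beta_{lk}, \hat R_l / n_k)$ per block, with
cross-trait covariance $\rho_o \hat R_l / \sqrt{n_1 n_2}$ under overlap
(the symmetric $\sqrt{n_1 n_2}$ resolves an ambiguous $/n_k$ in the
source); sampling uses the block eigendecomposition with negative
eigenvalues floored at zero.

Two reconstructions are documented as such: the per-class element values of
the four-matrix mixture are not printed in the available text, so they are
rebuilt from the design constraints — every SNP causal for trait $k$
contributes variance $h^2_{gk}/m_k$ with $m_k$ the realized causal count,
and SNPs causal for both traits share covariance
$r_g\sqrt{h^2_{g1} h^2_{g2}}/m_{\text{both}}$ — which makes the realized
heritabilities and genetic correlation hit their targets given the
assignment (the scaling factors are computed on the realized assignment,
removing one source of Monte-Carlo error; an expected-count mode exists).
These per-SNP matrices are positive semidefinite for all the design's
settings since $r_g \le P_\text{both}/\sqrt{P_1 P_2} \approx 0.73$.

Synthetic genotype panels come from a latent Gaussian copula: per
haplotype, an AR(1) latent process (coefficient `ld_decay`, default 0.7)
runs along each block's SNPs and an allele is called below the quantile of
the SNP's minor allele frequency (uniform in 0.05–0.5 by default), so SNPs
are in Hardy-Weinberg equilibrium marginally and in within-block LD.
Defaults of 50 SNPs per block keep desk-scale panels realistic in local LD
while staying cheap. What this does **not** emulate: real LD block-length
distributions, allele-frequency spectra skewed toward rare variants,
population stratification, genotyping error or imputation noise. Passing
tests therefore certify the estimator's internal consistency and its
behavior under the stated generative model, not performance on any real
cohort.

## Problem sizes used in the tests and acceptance script

Test fixtures use panels of 100–2,000 subjects and 8–20,000 SNPs. The
directional end-to-end comparison runs ten replicates at 20,000 SNPs with
GWAS-equivalent n of 5,000 and 2,000-subject reference/test panels — a
scaled-down analogue of the full design chosen so the whole suite stays
desk-sized. The acceptance script simulates its 200,000-subject test cohort
in 5,000-subject chunks (the affected fractions are sums over chunks, so
chunking is exact), measures realized heritabilities on 5,000-subject
panels, and the genetic correlation on a 50,000-SNP draw.

## Known limitations

* Residual covariances between traits are fixed at 0 (traits measured on
  different samples do not identify them).
* Per-trait penalty values share a single $\lambda$ by default (the
  combined selection criterion); per-trait selection is available behind a
  flag but untested against the reference design.
* The extra ridge multiplier on the $\beta^\top \Sigma_{bj}^{-1}\beta$ term
  discussed as future work in the source material is not implemented.
* X-chromosome handling, meta-analysis, genomic control and INFO filtering
  are out of scope; the full published annotation sets (BLD-X) are not
  shipped — the annotation machinery accepts any user table.
```
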