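# mvlassosum

Sparse polygenic risk scores (PRSs) for several genetically correlated
traits, built jointly from GWAS summary statistics.

## What it does and for whom

Single-trait PRS methods leave information on the table when disorders
share genetic architecture — schizophrenia and bipolar disorder being the
canonical pair. `mvlassosum` is for statistical geneticists who have, per
trait, only published GWAS summary statistics (effect sizes and standard
errors, p values with signs, or Z scores, plus sample sizes), a reference
genotype panel in PLINK 1 bed/bim/fam format for linkage disequilibrium
(LD), and optionally a table of per-SNP genomic annotations.

SNP effects across the $q$ traits are modelled as correlated random
effects, $\beta_j \sim N(0, \Sigma_{bj})$ with a per-SNP $q \times q$
genetic covariance matrix, and estimated by minimizing a penalized
multivariate objective on SNP–trait correlations $r_{jk}$:

$$
f(\beta) = \sum_j \beta_j^\top \Sigma_{bj}^{-1} \beta_j
 - 2 \sum_j \beta_j^\top \Sigma_s^{-1} \mathrm{diag}(n)\, r_j
 + \sum_{j,l} \beta_j^\top \mathrm{diag}(n) \big(\tilde X_j^\top \tilde X_l
 + s\,\mathbb{1}_{j=l}\big) \Sigma_s^{-1} \beta_l
 + 2\lambda \lVert W \beta \rVert_1 ,
$$

an elastic-net problem solved by block-wise coordinate descent (in C++),
with warm-started penalty paths, adaptive-LASSO weights, and KKT
optimality certificates. The matrices $\Sigma_{bj}$ are either constant
across SNPs or predicted from annotations via cross-trait stratified
LD-score regression; $\lambda$ is tuned without individual-level data by
splitting the summary statistics into pseudo training/validation parts. A
simulation module generates LD-structured genotype panels, causal-mixture
effects, region-wise summary statistics (with optional sample-overlap
correlation) and liability-threshold case-control cohorts.

See `vignettes/multitrait-prs-methods.Rmd` for the model, numerical
choices, and what the simulator does and does not emulate.

## Worked example

A self-contained run on synthetic data — a 2,000-SNP panel, two correlated
traits with heritabilities 0.47/0.45 and genetic correlation 0.59,
constant covariance model, pseudo-split tuning:

```r
library(mvlassosum)

fx <- make_fixture_panel(n_subjects = 1000, p_snps = 2000, block_size = 50,
                         seed = 42)
scen <- simulation_scenario()            # high-heritability reference setting
status <- assign_causal_status(scen, 2000, seed = 1)
effects <- draw_effects(status, scen, seed = 2)
ss <- draw_region_sumstats(effects, fx$ld, n = c(20000, 20000), seed = 3)

split <- pseudo_split(ss, fx$panel, nB_fraction = 0.1, seed = 4)
model <- constant_covariance_model(matrix(c(0.47, 0.27, 0.27, 0.45), 2), 2000)
grid <- lambda_grid(split, fx$ld, model, n_points = 20)
fit <- grid$fit
fit
#> mvl_fit: 2000 SNPs x 2 traits, 20 lambda values
#>   nonzero proportion range: 0.000 - 0.949 ; converged: 20 / 20

sel <- select_model(list(constant = fit), split, fx$panel)
sel
#> selection_report: 20 candidate fits
#>   selected: constant at lambda = 27.95 (criterion 1.0065)

test <- make_fixture_panel(1000, 2000, block_size = 50, seed = 99,
                           compute_ld = FALSE)
cohort <- simulate_liability_cohort(effects, test$panel, seed = 5)
prs <- score_prs(sel$beta, test$panel)
evaluate_prs(prs, cohort)
#>   trait cor_with_G       auc
#> 1     1  0.8778957 0.8824980
#> 2     2  0.8811364 0.9252234
```

Reading the output: the path of 20 penalty values runs from the all-zero
solution down to ~95% of SNPs selected; the pseudo-validation criterion
picks `lambda = 27.95`. On an independent 1,000-subject test cohort the
selected score correlates 0.88 with each trait's true genetic predictor
and separates affected from unaffected subjects with AUCs of 0.88 and 0.93
(the traits have 1% and 2% prevalence under the liability threshold
model). Numbers are exactly reproducible with these seeds.

Real data enter through `read_sumstats()` + `to_correlation()` +
`harmonize_sumstats()` (allele alignment, strand-ambiguity filtering) and
`read_plink()` + `partition_blocks()` (interval files, e.g.
Berisa–Pickrell blocks, or a fixed SNP window). A thin command-line
wrapper is installed at `inst/cli/mvlassosum` with subcommands `fixture`,
`simulate`, `pseudosplit`, `covmodel`, `fit`, `score`, `evaluate`; every
run writes a `manifest.json` with resolved arguments, input digests and
seed.

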