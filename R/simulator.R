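## End-to-end simulation machinery: scenario definitions, causal-mixture SNP
## effects, region-wise summary statistics with optional sample overlap,
## liability-threshold cohorts, PRS evaluation, and a synthetic genotype
## fixture generator.

#' Define a two-trait simulation scenario
#'
#' Default values are the reference study conditions: observed-scale SNP
#' heritabilities (0.47, 0.45) for the high setting or (0.10, 0.09) for the
#' low one; proportions of SNPs influencing each trait (0.49, 0.47) with
#' P(causal for both) = 0.35 for high polygenicity, or (0.12, 0.10) with 0.08
#' for low; target genetic correlation 0.59 (high) or 0.44 (moderate) under
#' the four-covariance-matrix mixture; trait prevalences 1% and 2%; no sample
#' overlap (`rho_o = 0`; the sensitivity settings use 0.16 and 0.32); GWAS
#' sample sizes 23,330 per trait with reference and test panels of 3,000.
#'
#' @param heritability `"high"`, `"low"`, or a length-2 numeric vector.
#' @param polygenicity `"high"`, `"low"`, or a list with `p1`, `p2`, `p_both`.
#' @param covariance_mode `"four_matrix"` (causal-mixture with constant
#'   per-class matrices) or `"annotation"` (per-SNP contributions supplied to
#'   [draw_effects()]).
#' @param rg target genetic correlation for the four-matrix mode.
#' @param rho_o between-trait summary-statistic correlation induced by sample
#'   overlap (0, 0.16 or 0.32 in the study settings).
#' @param prevalence length-2 trait prevalences.
#' @param n_gwas length-2 GWAS sample sizes.
#' @param n_ref,n_test reference-panel and test-cohort sizes.
#' @param seed scenario seed.
#' @return a `simulation_scenario` list.
#' @export
simulation_scenario <- function(heritability = "high", polygenicity = "high",
                                covariance_mode = c("four_matrix", "annotation"),
                                rg = 0.59, rho_o = 0,
                                prevalence = c(0.01, 0.02),
                                n_gwas = c(23330, 23330),
                                n_ref = 3000, n_test = 3000, seed = NULL) {
  covariance_mode <- match.arg(covariance_mode)
  h2 <- if (is.character(heritability)) {
    switch(match.arg(heritability, c("high", "low")),
           high = c(0.47, 0.45), low = c(0.10, 0.09))
  } else as.numeric(heritability)
  assert_that(length(h2) == 2L && all(h2 > 0 & h2 < 1),
              "heritabilities must lie in (0, 1)")
  pg <- if (is.character(polygenicity)) {
    switch(match.arg(polygenicity, c("high", "low")),
           high = list(p1 = 0.49, p2 = 0.47, p_both = 0.35),
           low = list(p1 = 0.12, p2 = 0.10, p_both = 0.08))
  } else polygenicity
  probs <- c(both = pg$p_both, t1 = pg$p1 - pg$p_both, t2 = pg$p2 - pg$p_both)
  probs <- c(probs, none = 1 - sum(probs))
  assert_that(all(probs >= 0) && all(probs <= 1),
              "causal-status probabilities must be valid (check p1, p2, p_both)")
  assert_that(abs(rg) <= 1, "|rg| must be at most 1")
  assert_that(all(prevalence > 0 & prevalence < 1),
              "prevalences must lie in (0, 1)")
  structure(list(q = 2L, h2 = h2, polygenicity = pg, status_probs = probs,
                 covariance_mode = covariance_mode, rg = rg, rho_o = rho_o,
                 prevalence = prevalence, n_gwas = as.numeric(n_gwas),
                 n_ref = n_ref, n_test = n_test, seed = seed),
            class = "simulation_scenario")
}

#' Assign per-SNP causal status
#'
#' Independent multinomial assignment over \{both, trait 1 only, trait 2 only,
#' none\}. In annotation mode, a SNP whose predicted heritability is
#' non-positive for a trait is demoted to non-causal for that trait.
#'
#' @param scenario a `simulation_scenario`.
#' @param p number of SNPs.
#' @param contributions p x 3 matrix (`h2_1`, `h2_2`, `rho`) of per-SNP
#'   predictions; required in annotation mode.
#' @param seed RNG seed.
#' @return factor of length p with levels `none`, `t1`, `t2`, `both`.
#' @export
assign_causal_status <- function(scenario, p, contributions = NULL,
                                 seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  local_seed(seed)
  pr <- scenario$status_probs
  status <- sample(factor(c("both", "t1", "t2", "none"),
                          levels = c("none", "t1", "t2", "both")),
                   size = p, replace = TRUE,
                   prob = pr[c("both", "t1", "t2", "none")])
  if (scenario$covariance_mode == "annotation") {
    assert_that(!is.null(contributions),
                "annotation mode requires per-SNP contributions")
    h1_ok <- contributions[, 1] > 0
    h2_ok <- contributions[, 2] > 0
    status[status == "both" & !h1_ok] <- "t2"
    status[status == "both" & !h2_ok] <- "t1"
    status[status == "t1" & !h1_ok] <- "none"
    status[status == "t2" & !h2_ok] <- "none"
    status[status == "both" & !h1_ok & !h2_ok] <- "none"
  }
  status
}

#' Draw correlated SNP effects under the causal mixture
#'
#' For the four-matrix mode, every SNP causal for trait k contributes the
#' same variance `h2_k / m_k` (with `m_k` the realized count of SNPs causal
#' for trait k), and SNPs causal for both traits share covariance
#' `rg sqrt(h2_1 h2_2) / m_both`, so the realized heritabilities and genetic
#' correlation match their targets in expectation given the assignment. For
#' the annotation mode, per-SNP contributions are scaled by `alpha_k = h2_k /
#' sum of contributions over causal SNPs` and the covariance by
#' `alpha = sqrt(alpha_1 alpha_2)`, clamped to keep each 2 x 2 matrix
#' positive semidefinite.
#'
#' @param status factor from [assign_causal_status()].
#' @param scenario a `simulation_scenario`.
#' @param contributions p x 3 matrix, required in annotation mode.
#' @param seed RNG seed.
#' @param alpha_mode `"realized"` (default; scale on the realized causal
#'   counts) or `"expected"` (scale on expected counts `p * P_k`).
#' @return an `effect_draw`: list with `status`, `beta` (p x 2), `alpha`
#'   (alpha_1, alpha_2, alpha).
#' @export
draw_effects <- function(status, scenario, contributions = NULL, seed = NULL,
                         alpha_mode = c("realized", "expected")) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  alpha_mode <- match.arg(alpha_mode)
  local_seed(seed)
  p <- length(status)
  beta <- matrix(0, p, 2)
  c1 <- status %in% c("t1", "both")
  c2 <- status %in% c("t2", "both")
  cb <- status == "both"
  h2 <- scenario$h2

  if (scenario$covariance_mode == "four_matrix") {
    m1 <- if (alpha_mode == "realized") sum(c1) else p * scenario$polygenicity$p1
    m2 <- if (alpha_mode == "realized") sum(c2) else p * scenario$polygenicity$p2
    mb <- if (alpha_mode == "realized") sum(cb) else p * scenario$polygenicity$p_both
    assert_that(m1 > 0 && m2 > 0, "no causal SNPs drawn; increase p")
    v1 <- h2[1] / m1
    v2 <- h2[2] / m2
    cv <- if (mb > 0) scenario$rg * sqrt(h2[1] * h2[2]) / mb else 0
    cap <- sqrt(v1 * v2)
    if (abs(cv) > cap) {
      warning("per-SNP covariance clamped to keep the effect matrix PSD",
              call. = FALSE)
      cv <- sign(cv) * cap
    }
    # bivariate draw for 'both' SNPs via conditional factorization
    nb <- sum(cb)
    if (nb > 0) {
      b1 <- rnorm(nb, 0, sqrt(v1))
      b2 <- cv / v1 * b1 + rnorm(nb, 0, sqrt(max(v2 - cv^2 / v1, 0)))
      beta[cb, 1] <- b1
      beta[cb, 2] <- b2
    }
    beta[status == "t1", 1] <- rnorm(sum(status == "t1"), 0, sqrt(v1))
    beta[status == "t2", 2] <- rnorm(sum(status == "t2"), 0, sqrt(v2))
    alpha <- c(alpha1 = v1 * m1 / h2[1], alpha2 = v2 * m2 / h2[2], alpha = 1)
  } else {
    assert_that(!is.null(contributions),
                "annotation mode requires per-SNP contributions")
    h1j <- pmax(contributions[, 1], 0)
    h2j <- pmax(contributions[, 2], 0)
    rhoj <- contributions[, 3]
    s1 <- sum(h1j[c1]); s2 <- sum(h2j[c2])
    assert_that(s1 > 0 && s2 > 0, "no positive contributions among causal SNPs")
    a1 <- h2[1] / s1
    a2 <- h2[2] / s2
    a <- sqrt(a1 * a2)
    v1 <- a1 * h1j
    v2 <- a2 * h2j
    cv <- a * rhoj
    cap <- sqrt(v1 * v2)
    clamped <- abs(cv) > cap & cb
    if (any(clamped)) {
      warning(sum(clamped), " per-SNP covariance(s) clamped to keep the ",
              "effect matrices PSD", call. = FALSE)
      cv[clamped] <- sign(cv[clamped]) * cap[clamped]
    }
    nb <- sum(cb)
    if (nb > 0) {
      vb1 <- v1[cb]; vb2 <- v2[cb]; cvb <- cv[cb]
      b1 <- rnorm(nb, 0, sqrt(vb1))
      cond_var <- pmax(vb2 - cvb^2 / vb1, 0)
      b2 <- cvb / vb1 * b1 + rnorm(nb, 0, sqrt(cond_var))
      beta[cb, 1] <- b1
      beta[cb, 2] <- b2
    }
    i1 <- status == "t1"; i2 <- status == "t2"
    beta[i1, 1] <- rnorm(sum(i1), 0, sqrt(v1[i1]))
    beta[i2, 2] <- rnorm(sum(i2), 0, sqrt(v2[i2]))
    alpha <- c(alpha1 = a1, alpha2 = a2, alpha = a)
  }
  structure(list(status = status, beta = beta, alpha = alpha,
                 h2 = h2, scenario = scenario),
            class = "effect_draw")
}

#' Sample region-wise summary statistics given true effects
#'
#' Per LD block l and trait k, draws
#' `r_lk ~ N(R_l beta_lk, R_l / n_k)`; when `rho_o > 0` the two traits' noise
#' components share cross-covariance `rho_o R_l / sqrt(n_1 n_2)` (common
#' GWAS subjects induce correlated sampling noise). Sampling uses the
#' eigendecomposition of each block with negative eigenvalues floored at 0.
#'
#' @param effects an `effect_draw` (or a p x q coefficient matrix).
#' @param ld an `ld_block_set` aligned with the effect rows.
#' @param n length-q GWAS sample sizes.
#' @param rho_o overlap correlation (q = 2 only; default from the scenario or 0).
#' @param seed RNG seed.
#' @return a `summary_statistics` object (SNP ids taken from the block set).
#' @export
draw_region_sumstats <- function(effects, ld, n, rho_o = NULL, seed = NULL) {
  stopifnot(inherits(ld, "ld_block_set"))
  beta <- if (inherits(effects, "effect_draw")) effects$beta else as.matrix(effects)
  if (is.null(rho_o)) {
    rho_o <- if (inherits(effects, "effect_draw")) effects$scenario$rho_o else 0
  }
  q <- ncol(beta)
  assert_that(nrow(beta) == ld$p, "effects must align with the block set")
  assert_that(rho_o == 0 || q == 2L, "overlap correlation requires q = 2")
  assert_that(abs(rho_o) < 1, "|rho_o| must be below 1")
  local_seed(seed)
  r <- matrix(0, ld$p, q)
  for (l in seq_along(ld$blocks)) {
    ii <- ld$blocks[[l]]
    m <- length(ii)
    eg <- eigen(ld$R[[l]], symmetric = TRUE)
    sqrt_ev <- sqrt(pmax(eg$values, 0))
    S <- eg$vectors %*% (sqrt_ev * t(eg$vectors)) # R^(1/2)
    mu <- ld$R[[l]] %*% beta[ii, , drop = FALSE]
    z <- matrix(rnorm(m * q), m, q)
    if (rho_o != 0) {
      z[, 2] <- rho_o * z[, 1] + sqrt(1 - rho_o^2) * z[, 2]
    }
    for (k in seq_len(q)) {
      r[ii, k] <- mu[, k] + (S %*% z[, k]) / sqrt(n[k])
    }
  }
  summary_statistics(snp_id = ld$map$snp_id %||% paste0("snp", seq_len(ld$p)),
                     chrom = ld$map$chrom, pos = ld$map$pos,
                     a1 = ld$map$a1, a2 = ld$map$a2,
                     r = r, n = n, index = seq_len(ld$p))
}

#' Simulate a liability-threshold case-control cohort
#'
#' The liability of subject i for trait k is `L_ik = G_ik + E_ik` with
#' `G_ik = sum_j beta_jk x_ij` the true standardized genetic predictor and
#' `E_ik ~ N(0, 1 - h2_k)`. A subject is affected when its liability exceeds
#' the upper-prevalence quantile of the theoretical unit-variance liability
#' distribution (`qnorm(1 - K_k)`); with
#' `liability_standardize = "empirical"` the threshold is the empirical
#' quantile of the realized liabilities instead.
#'
#' @param effects an `effect_draw` (or p x 2 coefficient matrix; then `h2`
#'   and `prevalence` must be given).
#' @param panel a `genotype_panel` holding the cohort genotypes (panel-aligned
#'   with the effect rows).
#' @param prevalence length-2 prevalences; default from the effects' scenario.
#' @param h2 length-2 heritabilities; default from the effects' scenario.
#' @param seed RNG seed.
#' @param liability_standardize `"theoretical"` (default) or `"empirical"`.
#' @return a `liability_cohort`: list with `G`, `E`, `L` (n x 2 matrices),
#'   `affected` (n x 2 logical), `thresholds`.
#' @export
simulate_liability_cohort <- function(effects, panel, prevalence = NULL,
                                      h2 = NULL, seed = NULL,
                                      liability_standardize = c("theoretical", "empirical")) {
  liability_standardize <- match.arg(liability_standardize)
  stopifnot(inherits(panel, "genotype_panel"))
  if (inherits(effects, "effect_draw")) {
    h2 <- h2 %||% effects$h2
    prevalence <- prevalence %||% effects$scenario$prevalence
    beta <- effects$beta
  } else {
    beta <- as.matrix(effects)
    assert_that(!is.null(h2) && !is.null(prevalence),
                "h2 and prevalence required when effects is a plain matrix")
  }
  local_seed(seed)
  G <- score_prs(beta, panel)
  attr(G, "coverage") <- NULL
  n <- nrow(G); q <- ncol(G)
  E <- sapply(seq_len(q), function(k) rnorm(n, 0, sqrt(1 - h2[k])))
  L <- G + E
  thresholds <- if (liability_standardize == "theoretical") {
    qnorm(1 - prevalence)
  } else {
    vapply(seq_len(q), function(k) stats::quantile(L[, k], 1 - prevalence[k],
                                                   names = FALSE), numeric(1))
  }
  affected <- sweep(L, 2L, thresholds, ">")
  structure(list(G = G, E = E, L = L, affected = affected,
                 thresholds = thresholds, prevalence = prevalence, h2 = h2),
            class = "liability_cohort")
}

#' Mann-Whitney rank estimator of the AUC
#' @keywords internal
auc_rank <- function(scores, affected) {
  n1 <- sum(affected); n0 <- sum(!affected)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  rk <- rank(scores) # average ranks: ties count 1/2
  (sum(rk[affected]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate PRSs against a simulated cohort
#'
#' Per trait: Pearson correlation between the PRS and the true genetic
#' predictor `G`, and the AUC between affected and unaffected subjects by the
#' rank (Mann-Whitney) estimator.
#'
#' @param prs n x q score matrix from [score_prs()].
#' @param cohort a `liability_cohort`.
#' @return data.frame with one row per trait: `cor_with_G`, `auc`.
#' @export
evaluate_prs <- function(prs, cohort) {
  stopifnot(inherits(cohort, "liability_cohort"))
  prs <- as.matrix(prs)
  assert_that(nrow(prs) == nrow(cohort$G) && ncol(prs) == ncol(cohort$G),
              "PRS and cohort dimensions must agree")
  q <- ncol(prs)
  out <- data.frame(trait = seq_len(q), cor_with_G = NA_real_, auc = NA_real_)
  for (k in seq_len(q)) {
    if (sd(prs[, k]) == 0) {
      warning("PRS for trait ", k, " has zero variance; correlation undefined",
              call. = FALSE)
    } else {
      out$cor_with_G[k] <- cor(prs[, k], cohort$G[, k])
    }
    out$auc[k] <- auc_rank(prs[, k], cohort$affected[, k])
  }
  out
}

#' Generate a synthetic genotype panel in LD blocks
#'
#' Genotypes are built from a latent Gaussian copula: per haplotype, a
#' first-order autoregressive latent process with coefficient `ld_decay` runs
#' along the SNPs of each block (blocks are independent), and an allele is
#' called where the latent value falls below the quantile of the SNP's minor
#' allele frequency, drawn uniformly in `maf_range`. Genotypes are the sum of
#' two independent haplotypes, so each SNP is in Hardy-Weinberg equilibrium
#' marginally while adjacent SNPs within a block are in LD.
#'
#' @param n_subjects,p_snps panel dimensions.
#' @param block_size SNPs per LD block (default 50; the last block of a
#'   chromosome may be smaller).
#' @param ld_decay latent AR(1) coefficient in [0, 1) (default 0.7).
#' @param maf_range range of minor allele frequencies (default c(0.05, 0.5)).
#' @param seed RNG seed.
#' @param prefix when given, the panel is also written as a PLINK fileset
#'   (`<prefix>.bed/.bim/.fam`) and the block intervals as
#'   `<prefix>.blocks.tsv` (chrom, start, end; 0-based half-open).
#' @param compute_ld also compute per-block LD matrices (default `TRUE`).
#' @param s LD regularization stored in the block set (default 0.5).
#' @return list with `panel` (a `genotype_panel`), `blocks` (integer labels),
#'   and `ld` (an `ld_block_set`, or `NULL` when `compute_ld = FALSE`).
#' @export
make_fixture_panel <- function(n_subjects, p_snps, block_size = 50L,
                               ld_decay = 0.7, maf_range = c(0.05, 0.5),
                               seed = NULL, prefix = NULL, compute_ld = TRUE,
                               s = 0.5) {
  assert_that(n_subjects > 0 && p_snps > 0, "dimensions must be positive")
  assert_that(ld_decay >= 0 && ld_decay < 1, "ld_decay must be in [0, 1)")
  local_seed(seed)
  maf <- runif(p_snps, maf_range[1], maf_range[2])
  thr <- qnorm(maf)
  blocks <- ceiling(seq_len(p_snps) / block_size)
  latent_seed <- sample.int(.Machine$integer.max, 1L)
  geno <- .copula_genotypes(n_subjects, thr, as.integer(blocks), ld_decay,
                            latent_seed)
  # guard against monomorphic columns in small panels (all-0 or all-2;
  # constant heterozygous columns are not attainable from two haplotypes
  # at these sample sizes)
  f <- colMeans(geno)
  mono <- which(f == 0 | f == 2)
  for (j in mono) {
    i <- sample.int(n_subjects, 1L)
    geno[i, j] <- if (geno[i, j] == 0L) 1L else 1L
  }
  map <- data.frame(chrom = "1", snp_id = paste0("snp", seq_len(p_snps)),
                    pos = seq_len(p_snps) * 1000L,
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, map)
  if (!is.null(prefix)) {
    write_plink(panel, prefix)
    starts <- (match(unique(blocks), blocks) - 1L) * 1000L
    ends <- c(starts[-1], p_snps * 1000L + 1000L)
    data.table::fwrite(data.table::data.table("1", starts, ends),
                       paste0(prefix, ".blocks.tsv"), sep = "\t",
                       col.names = FALSE)
  }
  ld <- if (compute_ld) block_ld(panel, blocks, s = s) else NULL
  list(panel = panel, blocks = blocks, ld = ld)
}
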