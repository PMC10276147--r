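test_that("scenario presets encode the study design parameters", {
  scen <- simulation_scenario()
  expect_equal(scen$h2, c(0.47, 0.45))
  expect_equal(unname(scen$status_probs),
               c(0.35, 0.49 - 0.35, 0.47 - 0.35, 1 - 0.49 - 0.47 + 0.35))
  low <- simulation_scenario(heritability = "low", polygenicity = "low")
  expect_equal(low$h2, c(0.10, 0.09))
  expect_equal(unname(low$status_probs[1:3]), c(0.08, 0.04, 0.02))
  expect_equal(scen$prevalence, c(0.01, 0.02))
  expect_error(simulation_scenario(polygenicity = list(p1 = 0.1, p2 = 0.1,
                                                       p_both = 0.2)),
               "probabilities")
})

test_that("causal status frequencies match the multinomial probabilities", {
  scen <- simulation_scenario()
  p <- 50000L
  status <- assign_causal_status(scen, p, seed = 71)
  freq <- table(status) / p
  probs <- scen$status_probs[c("none", "t1", "t2", "both")]
  se <- sqrt(probs * (1 - probs) / p)
  expect_true(all(abs(freq - probs) <= 3 * se))
  # reproducible
  expect_identical(status, assign_causal_status(scen, p, seed = 71))
})

test_that("annotation mode demotes SNPs with non-positive predicted heritability", {
  scen <- simulation_scenario(covariance_mode = "annotation")
  p <- 2000L
  contrib <- cbind(h2_1 = rep(c(-1e-6, 1e-5), each = p / 2),
                   h2_2 = rep(1e-5, p), rho = 0)
  status <- assign_causal_status(scen, p, contributions = contrib, seed = 72)
  first_half <- status[1:(p / 2)]
  expect_false(any(first_half %in% c("t1", "both")))
  expect_true(any(status[(p / 2 + 1):p] == "both"))
})

test_that("effect draws respect the status pattern and hit the moment targets", {
  scen <- simulation_scenario() # high h2, high polygenicity, rg = 0.59
  p <- 20000L
  status <- assign_causal_status(scen, p, seed = 73)
  eff <- draw_effects(status, scen, seed = 74)
  expect_true(all(eff$beta[status == "none", ] == 0))
  expect_true(all(eff$beta[status == "t1", 2] == 0))
  expect_true(all(eff$beta[status == "t2", 1] == 0))

  # realized heritability: sum beta^2 ~ h2 with MC standard error h2 sqrt(2/m)
  m1 <- sum(status %in% c("t1", "both"))
  expect_lt(abs(sum(eff$beta[, 1]^2) - 0.47), 3 * 0.47 * sqrt(2 / m1))
  m2 <- sum(status %in% c("t2", "both"))
  expect_lt(abs(sum(eff$beta[, 2]^2) - 0.45), 3 * 0.45 * sqrt(2 / m2))
})

test_that("four-matrix mode hits the target genetic correlation", {
  for (rg in c(0.59, 0.44)) {
    scen <- simulation_scenario(rg = rg)
    p <- 20000L
    status <- assign_causal_status(scen, p, seed = 75)
    eff <- draw_effects(status, scen, seed = 76)
    rg_hat <- sum(eff$beta[, 1] * eff$beta[, 2]) /
      sqrt(sum(eff$beta[, 1]^2) * sum(eff$beta[, 2]^2))
    # MC error of the correlation over ~7000 'both' SNPs
    expect_lt(abs(rg_hat - rg), 3 * (1 - rg^2) / sqrt(sum(status == "both")))
  }
})

test_that("annotation-mode draws scale contributions to the target totals", {
  scen <- simulation_scenario(covariance_mode = "annotation")
  p <- 20000L
  set.seed(77)
  contrib <- cbind(h2_1 = rexp(p, 1e5), h2_2 = rexp(p, 1e5), rho = 0)
  contrib[, 3] <- 0.5 * sqrt(contrib[, 1] * contrib[, 2])
  status <- assign_causal_status(scen, p, contributions = contrib, seed = 78)
  eff <- draw_effects(status, scen, contributions = contrib, seed = 79)
  m1 <- sum(status %in% c("t1", "both"))
  expect_lt(abs(sum(eff$beta[, 1]^2) - 0.47), 3 * 0.47 * sqrt(2 / m1) * 2)
  expect_true(all(eff$beta[status == "none", ] == 0))
})

test_that("region-wise summary statistics have the prescribed moments", {
  fx <- make_fixture_panel(400, 30, block_size = 30, seed = 80)
  R <- fx$ld$R[[1]]
  set.seed(81)
  beta <- matrix(rnorm(60, 0, 0.02), 30, 2)
  n <- c(4000, 6000)
  reps <- 2000L
  r1 <- matrix(NA_real_, reps, 30)
  for (i in seq_len(reps)) {
    ss <- draw_region_sumstats(beta, fx$ld, n = n, seed = 1000 + i)
    r1[i, ] <- ss$r[, 1]
  }
  mu_hat <- colMeans(r1)
  mu <- as.numeric(R %*% beta[, 1])
  se <- sqrt(diag(R) / n[1] / reps)
  expect_true(all(abs(mu_hat - mu) <= 4 * se))
  # covariance close to R / n1 (elementwise, loose MC tolerance)
  S_hat <- cov(r1)
  expect_lt(max(abs(S_hat - R / n[1])), 6 * max(diag(R) / n[1]) / sqrt(reps) * 3)
})

test_that("sample overlap induces the prescribed cross-trait noise correlation", {
  fx <- make_fixture_panel(400, 40, block_size = 40, seed = 82)
  R <- fx$ld$R[[1]]
  eg <- eigen(R, symmetric = TRUE)
  keep <- eg$values > 1e-8
  # whitening operator for the block covariance
  W <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep])
  beta <- matrix(0, 40, 2)
  n <- c(5000, 5000)
  for (rho_o in c(0, 0.32)) {
    reps <- 800L
    z1 <- z2 <- NULL
    for (i in seq_len(reps)) {
      ss <- draw_region_sumstats(beta, fx$ld, n = n, rho_o = rho_o,
                                 seed = 2000 + i)
      z1 <- c(z1, W %*% (ss$r[, 1] * sqrt(n[1])))
      z2 <- c(z2, W %*% (ss$r[, 2] * sqrt(n[2])))
    }
    est <- cor(z1, z2)
    expect_lt(abs(est - rho_o), 3 / sqrt(length(z1)) + 0.02)
  }
})

test_that("liability cohorts use the prevalence thresholds and limits behave", {
  scen <- simulation_scenario()
  fx <- make_fixture_panel(20000, 2000, block_size = 40, seed = 83,
                           compute_ld = FALSE)
  status <- assign_causal_status(scen, 2000, seed = 84)
  eff <- draw_effects(status, scen, seed = 85)
  coh <- simulate_liability_cohort(eff, fx$panel, seed = 86)
  expect_equal(coh$thresholds, qnorm(c(0.99, 0.98)))
  for (k in 1:2) {
    K <- scen$prevalence[k]
    se <- sqrt(K * (1 - K) / 20000)
    expect_lt(abs(mean(coh$affected[, k]) - K), 4 * se + 0.005)
  }
  # h2 -> 0: affection independent of the genetic value
  eff0 <- eff
  eff0$beta <- eff$beta * 1e-6
  eff0$h2 <- c(1e-10, 1e-10)
  coh0 <- simulate_liability_cohort(eff0, fx$panel, seed = 87)
  expect_lt(abs(cor(coh0$G[, 1], as.numeric(coh0$affected[, 1]))), 0.03)
})

test_that("PRS evaluation: exact toys and agreement with an external AUC", {
  cohort <- structure(list(G = cbind(c(0, 1, 2, 0, 1), c(1, 0, 0, 2, 1)),
                           affected = cbind(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                                            c(FALSE, TRUE, FALSE, TRUE, FALSE))),
                      class = "liability_cohort")
  # PRS equal to G: correlation exactly 1
  m <- evaluate_prs(cohort$G, cohort)
  expect_equal(m$cor_with_G, c(1, 1))

  # toy AUC by exhaustive pair enumeration: cases {2,3}, controls {0,1,2}
  scores <- c(2, 3, 0, 1, 2)
  affected <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  cohort2 <- structure(list(G = cbind(scores, scores),
                            affected = cbind(affected, affected)),
                       class = "liability_cohort")
  m2 <- evaluate_prs(cbind(scores, scores), cohort2)
  expect_equal(m2$auc, c(11 / 12, 11 / 12))

  # rank estimator agrees with pROC on random data
  skip_if_not_installed("pROC")
  set.seed(88)
  sc <- rnorm(200)
  lab <- rbinom(200, 1, plogis(sc)) > 0
  auc_ext <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                            direction = "<")))
  cohort3 <- structure(list(G = cbind(sc), affected = cbind(lab)),
                       class = "liability_cohort")
  expect_equal(evaluate_prs(cbind(sc), cohort3)$auc, auc_ext)

  # zero-variance PRS: NA correlation with a warning
  expect_warning(expect_warning(
    m4 <- evaluate_prs(cbind(rep(0, 5), rep(0, 5)), cohort),
    "zero variance"), "zero variance")
  expect_true(all(is.na(m4$cor_with_G)))
})

test_that("fixture panels encode the requested LD structure and reproduce exactly", {
  # ld_decay = 0: off-diagonal LD near zero
  fx0 <- make_fixture_panel(800, 40, block_size = 20, ld_decay = 0, seed = 89)
  off0 <- abs(fx0$ld$R[[1]][upper.tri(fx0$ld$R[[1]])])
  expect_lt(mean(off0), 0.05)
  # stronger decay parameter -> stronger adjacent-SNP LD
  fx_lo <- make_fixture_panel(800, 40, block_size = 20, ld_decay = 0.2, seed = 90)
  fx_hi <- make_fixture_panel(800, 40, block_size = 20, ld_decay = 0.9, seed = 90)
  adj <- function(fx) {
    mean(vapply(fx$ld$R, function(R)
      mean(abs(R[cbind(1:(nrow(R) - 1), 2:nrow(R))])), numeric(1)))
  }
  expect_gt(adj(fx_hi), adj(fx_lo))
  # bit-identical reproduction under the same seed
  fx_a <- make_fixture_panel(100, 50, seed = 91)
  fx_b <- make_fixture_panel(100, 50, seed = 91)
  expect_identical(fx_a$panel$genotypes, fx_b$panel$genotypes)
  expect_identical(fx_a$panel$maf, fx_b$panel$maf)
})

test_that("the full simulation chain is reproducible under one seed", {
  run <- function() {
    fx <- make_fixture_panel(150, 100, block_size = 20, seed = 92)
    scen <- simulation_scenario()
    status <- assign_causal_status(scen, 100, seed = 93)
    eff <- draw_effects(status, scen, seed = 94)
    draw_region_sumstats(eff, fx$ld, n = c(10000, 10000), seed = 95)$r
  }
  expect_identical(run(), run())
})
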