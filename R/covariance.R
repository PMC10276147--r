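## Per-SNP genetic covariance matrices Sigma_bj and residual variances,
## either constant across SNPs or predicted from genomic annotations via
## cross-trait stratified LD-score regression.

#' Construct a genetic covariance model from per-SNP matrices
#'
#' @param sigma_b numeric array of dimension `c(q, q, p)`: per-SNP genetic
#'   variance/covariance contributions (trait-variance units).
#' @param trait_names optional length-q labels.
#' @param eps_floor invertibility floor added to the diagonal of degenerate
#'   matrices before inversion; default `1e-3 * h2_gk / p` per trait.
#' @return A `genetic_covariance_model`: list with `sigma_b`, `precision`
#'   (array `c(q, q, p)` of inverses after flooring), `heritabilities`
#'   (`h2_gk = sum_j (Sigma_bj)_kk`), `residual` (`1 - h2_gk`).
#' @export
genetic_covariance_model <- function(sigma_b, trait_names = NULL,
                                     eps_floor = NULL) {
  stopifnot(is.array(sigma_b), length(dim(sigma_b)) == 3L,
            dim(sigma_b)[1] == dim(sigma_b)[2])
  q <- dim(sigma_b)[1]; p <- dim(sigma_b)[3]
  h2 <- numeric(q)
  for (k in seq_len(q)) h2[k] <- sum(sigma_b[k, k, ])
  assert_that(all(h2 > 0 & h2 < 1),
              "per-trait heritabilities must lie in (0, 1)")
  floor_k <- eps_floor %||% (1e-3 * h2 / p)
  if (length(floor_k) == 1L) floor_k <- rep(floor_k, q)
  precision <- array(0, dim(sigma_b))
  min_eig <- Inf
  for (j in seq_len(p)) {
    S <- sigma_b[, , j]
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    min_eig <- min(min_eig, ev[q])
    if (ev[q] < max(floor_k) * 1e-6) S <- S + diag(floor_k, q)
    precision[, , j] <- solve(S)
    sigma_b[, , j] <- (sigma_b[, , j] + t(sigma_b[, , j])) / 2
  }
  assert_that(min_eig >= -1e-10,
              "per-SNP covariance matrices must be positive semidefinite")
  structure(list(sigma_b = sigma_b, precision = precision,
                 heritabilities = h2, residual = 1 - h2,
                 trait_names = trait_names %||% paste0("trait", seq_len(q)),
                 p = p, q = q),
            class = "genetic_covariance_model")
}

#' @export
print.genetic_covariance_model <- function(x, ...) {
  cat("genetic_covariance_model:", x$p, "SNPs x", x$q, "traits\n")
  cat("  h2_g =", paste(sprintf("%.4f", x$heritabilities), collapse = ", "),
      "; residual =", paste(sprintf("%.4f", x$residual), collapse = ", "), "\n")
  invisible(x)
}

#' Constant genetic covariance model
#'
#' Every SNP contributes the same matrix `totals / p`, where `totals` is the
#' q x q matrix of total heritabilities (diagonal) and genetic covariances
#' (off-diagonal).
#'
#' @param totals symmetric positive semidefinite q x q matrix with diagonal
#'   entries in (0, 1), e.g. `matrix(c(0.47, 0.27, 0.27, 0.45), 2)`.
#' @param p number of SNPs.
#' @inheritParams genetic_covariance_model
#' @export
constant_covariance_model <- function(totals, p, trait_names = NULL,
                                      eps_floor = NULL) {
  totals <- as.matrix(totals)
  assert_that(isSymmetric(totals, tol = 1e-10), "totals must be symmetric")
  ev <- eigen(totals, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) >= -1e-12, "totals must be positive semidefinite")
  assert_that(all(diag(totals) > 0 & diag(totals) < 1),
              "total heritabilities must lie in (0, 1)")
  q <- nrow(totals)
  sigma_b <- array(rep(totals / p, p), dim = c(q, q, p))
  genetic_covariance_model(sigma_b, trait_names = trait_names,
                           eps_floor = eps_floor)
}

#' Stratified LD scores of an annotation table
#'
#' Computes `l(j, C) = sum_l a_lC R_jl^2` under the block-diagonal LD model.
#'
#' @param annot p x C numeric matrix of annotation values; a baseline all-ones
#'   column must be present (added with a warning if absent).
#' @param ld an `ld_block_set` aligned with the annotation rows.
#' @return An `annotation_table`: list with `a` (p x C), `ld_scores` (p x C).
#' @export
annotation_ld_scores <- function(annot, ld) {
  annot <- as.matrix(annot)
  stopifnot(inherits(ld, "ld_block_set"))
  assert_that(nrow(annot) == ld$p, "annotation rows must match the panel SNPs")
  if (is.null(colnames(annot))) colnames(annot) <- paste0("C", seq_len(ncol(annot)))
  if (!any(apply(annot, 2L, function(x) all(x == 1)))) {
    warning("no baseline (all-ones) annotation found; adding one", call. = FALSE)
    annot <- cbind(baseline = 1, annot)
  }
  scores <- matrix(0, nrow(annot), ncol(annot), dimnames = dimnames(annot))
  for (l in seq_along(ld$blocks)) {
    ii <- ld$blocks[[l]]
    R2 <- ld$R[[l]]^2
    scores[ii, ] <- R2 %*% annot[ii, , drop = FALSE]
  }
  structure(list(a = annot, ld_scores = scores), class = "annotation_table")
}

#' Cross-trait stratified LD-score regression
#'
#' Estimates annotation effects on the genetic covariance of two traits and on
#' their heritabilities. The cross-trait fit regresses the per-SNP product of
#' Z scores on `sqrt(n1 n2) * l(j, C)`, plus (when `with_intercept`) a free
#' intercept `b12` absorbing the correlated sampling noise induced by sample
#' overlap; the overlap correlation is recoverable as `b12 / sqrt(b1 b2)`
#' with `b1`, `b2` the per-trait regression intercepts (near 1 without
#' confounding). The per-trait fits regress `Z_jk^2 - 1` on `n_k * l(j, C)`.
#'
#' @param z1,z2 per-SNP Z scores for the two traits (aligned with `annot`).
#' @param n1,n2 GWAS sample sizes.
#' @param annot an `annotation_table` from [annotation_ld_scores()].
#' @param with_intercept include the cross-trait intercept `b12`
#'   (default `FALSE`).
#' @param weights `"none"` (default) or `"baseline"` for 1/l(j, baseline)
#'   weights.
#' @return A `cross_trait_ldsc_fit`: list with `theta` (annotation effects on
#'   genetic covariance), `tau` (C x 2 matrix of effects on heritabilities),
#'   `b12`, `se_theta`, and the annotation column names.
#' @export
fit_cross_trait_ldsc <- function(z1, z2, n1, n2, annot,
                                 with_intercept = FALSE,
                                 weights = c("none", "baseline")) {
  stopifnot(inherits(annot, "annotation_table"))
  weights <- match.arg(weights)
  L <- annot$ld_scores
  C <- ncol(L)
  assert_that(length(z1) == nrow(L) && length(z2) == nrow(L),
              "Z scores must align with the annotation table")
  assert_that(nrow(L) >= C + 1L, "need more SNPs than annotation columns")
  w <- if (weights == "baseline") {
    base <- which(apply(annot$a, 2L, function(x) all(x == 1)))[1]
    1 / pmax(L[, base], 1)
  } else rep(1, nrow(L))

  design <- sqrt(n1 * n2) * L
  if (with_intercept) design <- cbind(design, intercept = 1)
  qrd <- qr(design * sqrt(w))
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop_input("rank-deficient LD-score design; collinear annotations: ",
               paste(bad, collapse = ", "))
  }
  fit12 <- lm.wfit(design, z1 * z2, w)
  theta <- fit12$coefficients[seq_len(C)]
  b12 <- if (with_intercept) fit12$coefficients[C + 1L] else 0
  # large-sample SE of the weighted LS coefficients (heteroscedasticity ignored)
  s2 <- sum(w * fit12$residuals^2) / fit12$df.residual
  XtWX <- crossprod(design * sqrt(w))
  se_all <- sqrt(diag(solve(XtWX)) * s2)

  tau <- matrix(NA_real_, C, 2, dimnames = list(colnames(L), c("tau1", "tau2")))
  se_tau <- tau
  for (k in 1:2) {
    nk <- if (k == 1L) n1 else n2
    zk <- if (k == 1L) z1 else z2
    dk <- nk * L
    fitk <- lm.wfit(dk, zk^2 - 1, w)
    tau[, k] <- fitk$coefficients
    s2k <- sum(w * fitk$residuals^2) / fitk$df.residual
    se_tau[, k] <- sqrt(diag(solve(crossprod(dk * sqrt(w)))) * s2k)
  }
  structure(list(theta = theta, tau = tau, b12 = b12,
                 se_theta = se_all[seq_len(C)],
                 se_b12 = if (with_intercept) se_all[C + 1L] else NA_real_,
                 se_tau = se_tau,
                 annotations = colnames(L), with_intercept = with_intercept),
            class = "cross_trait_ldsc_fit")
}

#' @export
print.cross_trait_ldsc_fit <- function(x, ...) {
  cat("cross_trait_ldsc_fit:", length(x$theta), "annotations",
      if (x$with_intercept) sprintf("(b12 = %.4g)", x$b12) else "(b12 fixed at 0)",
      "\n")
  print(data.frame(theta = x$theta, tau1 = x$tau[, 1], tau2 = x$tau[, 2],
                   row.names = x$annotations))
  invisible(x)
}

#' Predict raw per-SNP heritability and covariance contributions
#'
#' Linear predictions `h2_gk(j) = sum_C a_jC tau_kC` and
#' `rho_g(j) = sum_C a_jC theta_C`; values may be negative and are repaired by
#' [repair_and_scale()].
#'
#' @param fit a `cross_trait_ldsc_fit`.
#' @param annot the `annotation_table` the fit was made on (columns must match).
#' @return p x 3 matrix with columns `h2_1`, `h2_2`, `rho`.
#' @export
predict_snp_contributions <- function(fit, annot) {
  stopifnot(inherits(fit, "cross_trait_ldsc_fit"), inherits(annot, "annotation_table"))
  assert_that(identical(colnames(annot$a), fit$annotations),
              "annotation columns do not match the fit")
  cbind(h2_1 = as.numeric(annot$a %*% fit$tau[, 1]),
        h2_2 = as.numeric(annot$a %*% fit$tau[, 2]),
        rho  = as.numeric(annot$a %*% fit$theta))
}

#' Repair and rescale per-SNP contributions into a covariance model
#'
#' Negative predicted heritabilities are floored at 0. Where a predicted
#' covariance exceeds the per-SNP bound `sqrt(h2_1(j) h2_2(j))`, it is
#' replaced by `max(0, sqrt(h2_1(j) h2_2(j)) - 0.001)`; with the default
#' `sign_policy = "signed"` the bound is applied to the magnitude and the
#' predicted sign retained, while `"nonnegative"` applies the bound literally.
#' A SNP with either heritability equal to 0 gets covariance 0. The matrices
#' are then rescaled so per-trait sums equal `target_h2` (covariances scaled
#' by the geometric mean of the two trait factors), which leaves each SNP's
#' covariance-to-heritability ratio unchanged.
#'
#' @param raw p x 3 matrix from [predict_snp_contributions()].
#' @param target_h2 length-2 vector of target total heritabilities in (0, 1).
#' @param sign_policy `"signed"` (default) or `"nonnegative"`.
#' @inheritParams genetic_covariance_model
#' @return a `genetic_covariance_model`.
#' @export
repair_and_scale <- function(raw, target_h2, sign_policy = c("signed", "nonnegative"),
                             trait_names = NULL, eps_floor = NULL) {
  sign_policy <- match.arg(sign_policy)
  raw <- as.matrix(raw)
  assert_that(ncol(raw) == 3L, "raw contributions must have columns h2_1, h2_2, rho")
  assert_that(length(target_h2) == 2L && all(target_h2 > 0 & target_h2 < 1),
              "target heritabilities must lie in (0, 1)")
  h1 <- pmax(raw[, 1], 0)
  h2 <- pmax(raw[, 2], 0)
  rho <- raw[, 3]
  bound <- sqrt(h1 * h2)
  repaired_mag <- pmax(0, bound - 0.001)
  over <- abs(rho) > bound
  mag <- ifelse(over, repaired_mag, abs(rho))
  rho <- if (sign_policy == "signed") sign(rho) * mag else mag
  rho[h1 == 0 | h2 == 0] <- 0
  assert_that(sum(h1) > 0 && sum(h2) > 0,
              "all predicted heritabilities are non-positive")
  c1 <- target_h2[1] / sum(h1)
  c2 <- target_h2[2] / sum(h2)
  h1 <- h1 * c1
  h2 <- h2 * c2
  rho <- rho * sqrt(c1 * c2)
  p <- nrow(raw)
  sigma_b <- array(0, dim = c(2, 2, p))
  sigma_b[1, 1, ] <- h1
  sigma_b[2, 2, ] <- h2
  sigma_b[1, 2, ] <- sigma_b[2, 1, ] <- rho
  genetic_covariance_model(sigma_b, trait_names = trait_names,
                           eps_floor = eps_floor)
}

#' Serialize a covariance model as a per-SNP TSV plus JSON totals
#'
#' @param model a `genetic_covariance_model` (q = 2).
#' @param dir output directory.
#' @export
write_covariance_model <- function(model, dir) {
  stopifnot(inherits(model, "genetic_covariance_model"), model$q == 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- data.table::data.table(h2_1 = model$sigma_b[1, 1, ],
                               h2_2 = model$sigma_b[2, 2, ],
                               rho = model$sigma_b[1, 2, ])
  data.table::fwrite(dt, file.path(dir, "snp_contributions.tsv"), sep = "\t")
  jsonlite::write_json(list(heritabilities = model$heritabilities,
                            residual = model$residual,
                            trait_names = model$trait_names),
                       file.path(dir, "totals.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
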