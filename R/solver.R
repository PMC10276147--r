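## R interface to the coordinate-descent solver, the explicit objective,
## KKT optimality certificates, and adaptive penalty weights.

.as_training <- function(ss) {
  if (inherits(ss, "pseudo_split")) training_sumstats(ss) else ss
}

.check_aligned <- function(ss, ld, model) {
  assert_that(nrow(ss$r) == ld$p,
              "summary statistics and LD block set disagree on SNP count")
  assert_that(model$p == ld$p, "covariance model and LD block set disagree on SNP count")
  assert_that(model$q == ncol(ss$r),
              "covariance model and summary statistics disagree on trait count")
}

#' Fit the multivariate summary-statistic LASSO along a penalty path
#'
#' Minimizes, for each penalty value `lambda` (warm-started from the previous
#' one), the penalized objective combining (i) the summary-statistic quadratic
#' approximation of the multivariate regression likelihood with the
#' regularized block-diagonal LD operator `(1 - s) R + s I`, (ii) the
#' per-SNP genetic-covariance prior `beta_j' Sigma_bj^{-1} beta_j`, and
#' (iii) an L1 penalty `2 lambda |W beta|_1`. Coordinates are swept SNP-major
#' with active-set cycling; exact coordinate minimization makes the objective
#' non-increasing within each penalty value.
#'
#' @param ss a `summary_statistics` object (or a `pseudo_split`, in which case
#'   its training part is fitted), aligned to `ld`.
#' @param ld an `ld_block_set`.
#' @param model a `genetic_covariance_model`.
#' @param lambda descending vector of positive penalty values.
#' @param weights p x q matrix of non-negative penalty weights; `Inf` pins a
#'   coefficient at zero. Default all ones.
#' @param s LD regularization in (0, 1]; defaults to the value stored in `ld`.
#' @param cross_term_factor factor on the cross-trait precision term in the
#'   coordinate update; 1 (default) is the gradient of the stated objective,
#'   0.5 reproduces the alternative update rule. The monitored objective uses
#'   the quadratic form matching the chosen factor.
#' @param tol convergence tolerance on the maximum absolute coefficient change
#'   per sweep (standardized-genotype scale; default 1e-4).
#' @param maxit maximum sweeps per penalty value (default 100).
#' @param trace_objective record the objective after every sweep.
#' @return An `mvl_fit`: list with `beta` (p x q x n_lambda array), `lambda`,
#'   `iterations`, `converged`, `nonzero` (n_lambda x q proportions),
#'   `objective_trace`, plus the inputs needed for downstream scoring.
#' @export
mvl_fit <- function(ss, ld, model, lambda, weights = NULL, s = NULL,
                    cross_term_factor = 1, tol = 1e-4, maxit = 100L,
                    trace_objective = TRUE) {
  ss <- .as_training(ss)
  stopifnot(inherits(ss, "summary_statistics"), inherits(ld, "ld_block_set"),
            inherits(model, "genetic_covariance_model"))
  .check_aligned(ss, ld, model)
  s <- s %||% ld$s
  assert_that(s > 0 && s <= 1, "s must be in (0, 1]")
  assert_that(cross_term_factor %in% c(0.5, 1),
              "cross_term_factor must be 0.5 or 1")
  lambda <- as.numeric(lambda)
  assert_that(all(lambda > 0) && !is.unsorted(rev(lambda)),
              "lambda must be positive and descending")
  q <- ncol(ss$r)
  if (is.null(weights)) weights <- matrix(1, ld$p, q)
  weights <- as.matrix(weights)
  assert_that(all(dim(weights) == c(ld$p, q)), "weights must be p x q")
  assert_that(all(weights > 0 | is.infinite(weights)),
              "finite weights must be positive")

  res <- .cd_solve(ld$R, lapply(ld$blocks, function(ii) ii - 1L),
                   ss$r, ss$n, model$residual, model$precision,
                   weights, lambda, s, cross_term_factor, tol,
                   as.integer(maxit), trace_objective)
  nonzero <- t(apply(res$beta, 3L, function(b) colMeans(b != 0)))
  if (q == 1L) nonzero <- matrix(nonzero, ncol = 1L)
  colnames(nonzero) <- ss$trait_names
  if (any(res$converged == 0L)) {
    warning("no convergence within ", maxit, " sweeps for ",
            sum(res$converged == 0L), " lambda value(s)", call. = FALSE)
  }
  structure(list(beta = res$beta, lambda = lambda,
                 iterations = as.integer(res$iterations),
                 converged = as.logical(res$converged),
                 nonzero = nonzero,
                 objective_trace = res$objective_trace,
                 ld_cache = res$ld_cache,
                 weights = weights, s = s,
                 cross_term_factor = cross_term_factor,
                 snp_id = ss$snp_id, index = ss$index,
                 trait_names = ss$trait_names, n = ss$n),
            class = "mvl_fit")
}

#' @export
print.mvl_fit <- function(x, ...) {
  cat("mvl_fit:", dim(x$beta)[1], "SNPs x", dim(x$beta)[2], "traits,",
      length(x$lambda), "lambda values\n")
  cat("  nonzero proportion range:",
      sprintf("%.3f - %.3f", min(x$nonzero), max(x$nonzero)),
      "; converged:", sum(x$converged), "/", length(x$lambda), "\n")
  invisible(x)
}

.nsig <- function(ss, model) ss$n / model$residual

.cross_matrix <- function(beta, model, cross_term_factor, diag_zero = TRUE) {
  # rows j: sum_{h != k} P_kh(j) beta_jh, times the cross-term factor
  p <- nrow(beta); q <- ncol(beta)
  out <- matrix(0, p, q)
  for (k in seq_len(q)) {
    for (h in seq_len(q)) {
      if (h == k) next
      out[, k] <- out[, k] + model$precision[k, h, ] * beta[, h]
    }
  }
  cross_term_factor * out
}

#' Explicit solver objective (modulo the data-dependent constant)
#'
#' Evaluates the penalized objective the coordinate updates minimize, up to
#' the constant term that does not involve the coefficients. Used for descent
#' monitoring and oracle comparisons.
#'
#' @inheritParams mvl_fit
#' @param beta p x q coefficient matrix.
#' @param lambda single penalty value.
#' @return scalar objective value.
#' @export
mvl_objective <- function(beta, ss, ld, model, lambda, weights = NULL,
                          s = NULL, cross_term_factor = 1) {
  ss <- .as_training(ss)
  .check_aligned(ss, ld, model)
  s <- s %||% ld$s
  beta <- as.matrix(beta)
  q <- ncol(beta)
  if (is.null(weights)) weights <- matrix(1, nrow(beta), q)
  nsig <- .nsig(ss, model)
  U <- ld_multiply(ld, beta)
  prior <- 0
  for (k in seq_len(q)) {
    prior <- prior + sum(model$precision[k, k, ] * beta[, k]^2)
    if (k < q) for (h in seq((k + 1), q)) {
      prior <- prior + 2 * cross_term_factor *
        sum(model$precision[k, h, ] * beta[, k] * beta[, h])
    }
  }
  quad <- sum(nsig * ((1 - s) * colSums(beta * U) + s * colSums(beta^2)))
  lin <- sum(nsig * colSums(ss$r * beta))
  wb <- weights * abs(beta)
  pen <- sum(wb[is.finite(wb)])
  prior + quad - 2 * lin + 2 * lambda * pen
}

#' Karush-Kuhn-Tucker optimality certificate for a fitted path
#'
#' For every coefficient and penalty value, verifies the stationarity
#' conditions of the coordinate-wise objective: zero coefficients must have
#' `|A| <= lambda w + tol`, nonzero ones
#' `|A - D beta - lambda w sign(beta)| <= tol`.
#'
#' @param fit an `mvl_fit`.
#' @inheritParams mvl_fit
#' @param tol violation tolerance (default 1e-6).
#' @return data.frame with one row per penalty value: counts of violations,
#'   the maximum violation magnitude, and the count of zero coefficients
#'   active at the threshold (`|A|` within tol of `lambda w`).
#' @export
kkt_check <- function(fit, ss, ld, model, tol = 1e-6) {
  ss <- .as_training(ss)
  stopifnot(inherits(fit, "mvl_fit"))
  .check_aligned(ss, ld, model)
  s <- fit$s
  nsig <- .nsig(ss, model)
  dR <- ld_diag(ld)
  out <- data.frame(lambda = fit$lambda, n_violations = 0L,
                    max_violation = 0, at_threshold = 0L)
  for (il in seq_along(fit$lambda)) {
    beta <- fit$beta[, , il, drop = FALSE]
    dim(beta) <- dim(fit$beta)[1:2]
    U <- ld_multiply(ld, beta)
    ld_term <- (1 - s) * (U - dR * beta)
    A <- sweep(ss$r - ld_term, 2L, nsig, "*") -
      .cross_matrix(beta, model, fit$cross_term_factor)
    D <- outer(( 1 - s) * dR + s, nsig) + t(apply(model$precision, 3L, diag))
    lw <- fit$lambda[il] * fit$weights
    viol <- ifelse(beta == 0,
                   pmax(abs(A) - lw, 0),
                   abs(A - D * beta - lw * sign(beta)))
    viol[is.infinite(fit$weights)] <- 0 # pinned coefficients are uncontested
    out$n_violations[il] <- sum(viol > tol)
    out$max_violation[il] <- max(viol)
    out$at_threshold[il] <- sum(beta == 0 & is.finite(lw) &
                                  abs(abs(A) - lw) <= tol)
  }
  out
}

#' Adaptive LASSO penalty weights
#'
#' `w_jk = |source_jk|^(-gamma)`; a zero source coefficient yields an infinite
#' weight, pinning that coefficient at zero.
#'
#' @param source p x q matrix of preliminary effect estimates (e.g. GWAS
#'   betas, or the coefficients of a constant-penalty [mvl_fit()] at the
#'   selected penalty), or an `mvl_fit` (its last path entry is used).
#' @param gamma non-negative adaptive exponent (default 1).
#' @param lambda_index path entry to take when `source` is an `mvl_fit`.
#' @return p x q weight matrix.
#' @export
adaptive_weights <- function(source, gamma = 1, lambda_index = NULL) {
  assert_that(gamma >= 0, "gamma must be non-negative")
  if (inherits(source, "mvl_fit")) {
    il <- lambda_index %||% length(source$lambda)
    b <- source$beta[, , il, drop = FALSE]
    dim(b) <- dim(source$beta)[1:2]
    source <- b
  }
  source <- as.matrix(source)
  w <- abs(source)^(-gamma)
  w[source == 0] <- Inf
  w
}

#' Write path coefficients as a long-format TSV
#'
#' @param fit an `mvl_fit`.
#' @param path output file.
#' @param maf optional per-SNP minor allele frequencies; when given, an
#'   allele-count-scale column `beta_allele = beta / sqrt(2 maf (1 - maf))` is
#'   added to the standardized-scale coefficients.
#' @export
write_coefficients <- function(fit, path, maf = NULL) {
  stopifnot(inherits(fit, "mvl_fit"))
  p <- dim(fit$beta)[1]; q <- dim(fit$beta)[2]
  rows <- vector("list", length(fit$lambda) * q)
  i <- 0L
  for (il in seq_along(fit$lambda)) for (k in seq_len(q)) {
    i <- i + 1L
    b <- fit$beta[, k, il]
    rows[[i]] <- data.table::data.table(snp_id = fit$snp_id,
                                        trait = fit$trait_names[k],
                                        lambda = fit$lambda[il],
                                        beta = b)
    if (!is.null(maf)) rows[[i]]$beta_allele <- b / sqrt(2 * maf * (1 - maf))
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}
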