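## Penalty grids, the pseudo-validation selection criterion, PRS scoring,
## and final model selection.

#' Build a penalty grid satisfying the sparsity floor
#'
#' The largest penalty is the smallest value with an all-zero solution,
#' `lambda_max = max_jk |A0_jk| / w_jk` with `A0` the coordinate numerator at
#' `beta = 0`. Values are log-spaced downward; when `check_floor` is set the
#' path is fitted and extended until the smallest penalty yields at least
#' `floor` nonzero coefficients per trait (a warning is emitted if the floor
#' is unreachable).
#'
#' @inheritParams mvl_fit
#' @param n_points number of penalty values (default 20).
#' @param floor minimum nonzero proportion per trait required at the smallest
#'   penalty (default 0.05).
#' @param min_ratio initial ratio `lambda_min / lambda_max` (default 0.01).
#' @param check_floor fit the path to verify/extend the grid (default `TRUE`).
#' @param ... further arguments passed to [mvl_fit()] when checking the floor.
#' @return list with `lambda` (descending grid), and when `check_floor` the
#'   verification `fit` and its `nonzero` proportions.
#' @export
lambda_grid <- function(ss, ld, model, n_points = 20L, floor = 0.05,
                        weights = NULL, min_ratio = 0.01, check_floor = TRUE,
                        ...) {
  ss <- .as_training(ss)
  .check_aligned(ss, ld, model)
  assert_that(n_points >= 2L, "n_points must be at least 2")
  q <- ncol(ss$r)
  if (is.null(weights)) weights <- matrix(1, ld$p, q)
  A0 <- sweep(ss$r, 2L, .nsig(ss, model), "*")
  ratio <- abs(A0) / weights # Inf weights give 0, excluded automatically
  lam_max <- max(ratio[is.finite(ratio)])
  assert_that(is.finite(lam_max) && lam_max > 0,
              "cannot determine lambda_max (all coefficients pinned?)")
  grid <- exp(seq(log(lam_max), log(lam_max * min_ratio),
                  length.out = n_points))
  grid[1] <- lam_max # exact: exp(log(x)) can drop an ulp below x
  if (!check_floor) return(list(lambda = grid))
  fit <- mvl_fit(ss, ld, model, grid, weights = weights, ...)
  step <- log(grid[1] / grid[2])
  bound <- log(lam_max * 1e-8)
  while (any(fit$nonzero[nrow(fit$nonzero), ] < floor)) {
    lo <- log(min(grid))
    if (lo - step < bound) {
      warning("sparsity floor of ", floor,
              " not reachable within the penalty bounds; returning the ",
              "best-effort grid", call. = FALSE)
      break
    }
    ext <- exp(seq(lo - step, max(lo - step * n_points, bound), by = -step))
    grid <- c(grid, ext)
    fit <- mvl_fit(ss, ld, model, grid, weights = weights, ...)
  }
  list(lambda = grid, fit = fit, nonzero = fit$nonzero)
}

.beta_slice <- function(fit, il) {
  b <- fit$beta[, , il, drop = FALSE]
  dim(b) <- dim(fit$beta)[1:2]
  b
}

#' Pseudo-validation selection criterion
#'
#' Evaluates `f = (sum_k beta_k' rB_k) / sqrt((1/n0) sum_k |X0 beta_k|^2)`,
#' the summary-statistic surrogate for the correlation between the PRS and
#' the trait in a validation sample, with `rB` the pseudo-validation
#' correlations and `X0` the standardized genotypes of an independent panel.
#' An all-zero coefficient matrix returns `-Inf` (excluded from selection).
#'
#' @param beta p x q coefficient matrix.
#' @param rB p x q pseudo-validation correlations (or a `pseudo_split`).
#' @param panel0 validation `genotype_panel`.
#' @param index panel column indices of the coefficient SNPs (default: taken
#'   from `rB` when it is a `pseudo_split`, else 1..p).
#' @param X0 optional precomputed `standardize_panel(panel0, index)` matrix,
#'   reused across a path to avoid re-standardizing the panel per penalty.
#' @return list with `criterion` (scalar) and `per_trait` diagnostics
#'   (numerator, denominator and ratio per trait).
#' @export
selection_criterion <- function(beta, rB, panel0, index = NULL, X0 = NULL) {
  stopifnot(inherits(panel0, "genotype_panel"))
  if (inherits(rB, "pseudo_split")) {
    index <- index %||% rB$index
    rB <- rB$rB
  }
  beta <- as.matrix(beta)
  rB <- as.matrix(rB)
  assert_that(all(dim(beta) == dim(rB)), "beta and rB must have equal dimensions")
  index <- index %||% seq_len(nrow(beta))
  assert_that(length(index) == nrow(beta) && max(index) <= ncol(panel0$genotypes),
              "panel0 does not cover the coefficient SNPs")
  if (all(beta == 0)) {
    return(list(criterion = -Inf,
                per_trait = data.frame(numerator = rep(0, ncol(beta)),
                                       denominator = 0, ratio = -Inf)))
  }
  if (is.null(X0)) X0 <- standardize_panel(panel0, index)
  G <- X0 %*% beta
  num_k <- colSums(beta * rB)
  den_k <- colSums(G^2) / panel0$n_r
  list(criterion = sum(num_k) / sqrt(sum(den_k)),
       per_trait = data.frame(numerator = num_k, denominator = den_k,
                              ratio = ifelse(den_k > 0,
                                             num_k / sqrt(den_k), -Inf),
                              row.names = colnames(beta) %||%
                                paste0("trait", seq_along(num_k))))
}

#' Score polygenic risk scores on a genotype panel
#'
#' `PRS_ik = sum_j beta_jk x_ij` on the standardized-genotype scale. SNPs
#' absent from the panel are skipped with a warning and the coverage fraction
#' is reported as an attribute.
#'
#' @param beta p x q coefficient matrix.
#' @param panel a `genotype_panel`.
#' @param snp_id SNP identifiers of the coefficient rows; matched against the
#'   panel map. When `NULL` the rows are assumed panel-aligned.
#' @param standardize_group optional subject indices; when given, each PRS
#'   column is shifted/scaled to mean 0, variance 1 within that group.
#' @return n x q matrix of scores with attribute `coverage`.
#' @export
score_prs <- function(beta, panel, snp_id = NULL, standardize_group = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  beta <- as.matrix(beta)
  if (is.null(snp_id)) {
    assert_that(nrow(beta) == ncol(panel$genotypes),
                "beta rows must match the panel when snp_id is not given")
    idx <- seq_len(nrow(beta))
    keep <- rep(TRUE, nrow(beta))
  } else {
    idx <- match(snp_id, panel$map$snp_id)
    keep <- !is.na(idx)
    if (!all(keep)) {
      warning(sum(!keep), " of ", length(keep),
              " coefficient SNPs missing from the panel; scored on the ",
              "intersection", call. = FALSE)
    }
    idx <- idx[keep]
  }
  X <- standardize_panel(panel, idx)
  prs <- X %*% beta[keep, , drop = FALSE]
  if (!is.null(standardize_group)) {
    mu <- colMeans(prs[standardize_group, , drop = FALSE])
    sg <- apply(prs[standardize_group, , drop = FALSE], 2L, sd)
    prs <- sweep(sweep(prs, 2L, mu, "-"), 2L, sg, "/")
  }
  attr(prs, "coverage") <- mean(keep)
  prs
}

#' Select the penalty and covariance model by the pseudo-validation criterion
#'
#' Evaluates [selection_criterion()] over every (model, lambda) pair and
#' returns the argmax. Ties are broken toward the largest penalty (sparsest
#' model) and then the first model in list order.
#'
#' @param fits named list of `mvl_fit` objects (one per covariance model).
#' @param rB p x q pseudo-validation correlations or a `pseudo_split`.
#' @param panel0 validation `genotype_panel`.
#' @param index see [selection_criterion()].
#' @return A `selection_report`: list with `table` (model, lambda, criterion,
#'   nonzero proportions per trait), `selected` (model label, lambda, lambda
#'   index) and `beta` (selected coefficient matrix).
#' @export
select_model <- function(fits, rB, panel0, index = NULL) {
  assert_that(length(fits) >= 1L, "at least one fitted path is required")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  rB_idx <- if (inherits(rB, "pseudo_split")) rB$index else NULL
  rows <- list()
  X0 <- NULL; X0_index <- NULL
  for (m in names(fits)) {
    fit <- fits[[m]]
    stopifnot(inherits(fit, "mvl_fit"))
    idx <- index %||% rB_idx %||% fit$index %||% seq_len(dim(fit$beta)[1])
    if (is.null(X0) || !identical(idx, X0_index)) {
      X0 <- standardize_panel(panel0, idx)
      X0_index <- idx
    }
    crit <- vapply(seq_along(fit$lambda), function(il) {
      selection_criterion(.beta_slice(fit, il), rB, panel0,
                          index = idx, X0 = X0)$criterion
    }, numeric(1))
    rows[[m]] <- data.frame(model = m, lambda = fit$lambda,
                            lambda_index = seq_along(fit$lambda),
                            criterion = crit, fit$nonzero,
                            check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- is.finite(tab$criterion)
  if (!any(ok)) stop_input("no admissible model: all criteria are -Inf")
  best <- which(ok & tab$criterion == max(tab$criterion[ok]))
  if (length(best) > 1L) best <- best[order(-tab$lambda[best])][1]
  sel <- tab[best, ]
  fit <- fits[[sel$model]]
  structure(list(table = tab,
                 selected = list(model = sel$model, lambda = sel$lambda,
                                 lambda_index = sel$lambda_index,
                                 criterion = sel$criterion),
                 beta = .beta_slice(fit, sel$lambda_index),
                 snp_id = fit$snp_id, index = fit$index,
                 trait_names = fit$trait_names),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report:", nrow(x$table), "candidate fits\n")
  cat("  selected:", x$selected$model, "at lambda =",
      format(x$selected$lambda, digits = 4),
      sprintf("(criterion %.4f)\n", x$selected$criterion))
  invisible(x)
}

#' Serialize a selection report as TSV + JSON
#'
#' @param report a `selection_report`.
#' @param dir output directory.
#' @export
write_selection_report <- function(report, dir) {
  stopifnot(inherits(report, "selection_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$table, file.path(dir, "selection.tsv"), sep = "\t")
  jsonlite::write_json(report$selected, file.path(dir, "selected.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
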