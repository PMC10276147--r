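## LD block partitioning and per-block correlation matrices.
##
## Cross-block LD is ignored by construction: the solver and the region-wise
## summary-statistic sampler both operate on the block-diagonal approximation
## R = diag(R_1, ..., R_L), the convention of summary-statistic LASSO methods.

#' Partition the SNPs of a panel into LD blocks
#'
#' Blocks are either taken from a BED-like interval file (chrom, start, end;
#' 0-based half-open) or built by a fixed-window rule of `window` SNPs per
#' block within each chromosome.
#'
#' @param panel a `genotype_panel`.
#' @param block_file path to a 3-column interval file, or `NULL` to use the
#'   fixed-window rule.
#' @param window SNPs per block for the fixed-window rule (default 500).
#' @param strict if `TRUE`, a SNP falling outside every interval of its
#'   chromosome is an error; otherwise it is assigned to the nearest interval
#'   with a warning.
#' @return Integer vector of block labels (1-based, contiguous) of length p;
#'   SNP order is panel order.
#' @export
partition_blocks <- function(panel, block_file = NULL, window = 500L,
                             strict = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  chrom <- as.character(panel$map$chrom)
  pos <- panel$map$pos
  p <- length(pos)
  if (is.null(block_file)) {
    lab <- integer(p)
    nxt <- 0L
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      k <- ceiling(seq_along(idx) / window)
      lab[idx] <- nxt + k
      nxt <- nxt + max(k)
    }
    return(.relabel_blocks(lab))
  }
  iv <- data.table::fread(block_file, header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = list(character = 1))
  lab <- integer(p)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ivc <- iv[iv$chrom == ch, ]
    if (nrow(ivc) == 0L) stop_input("no LD block intervals for chromosome ", ch)
    ivc <- ivc[order(ivc$start), ]
    hit <- findInterval(pos[idx], ivc$start)
    inside <- hit >= 1L & pos[idx] < ivc$end[pmax(hit, 1L)]
    if (any(!inside)) {
      if (strict) {
        stop_input(sum(!inside), " SNPs outside all LD block intervals on chromosome ", ch)
      }
      warning(sum(!inside), " SNPs outside all intervals on chromosome ", ch,
              "; assigned to the nearest interval", call. = FALSE)
      mid <- (ivc$start + ivc$end) / 2
      for (w in which(!inside)) {
        hit[w] <- which.min(abs(pos[idx][w] - mid))
      }
    }
    # interval row -> global block label (offset by blocks of previous chroms)
    lab[idx] <- paste0(ch, ":", hit)
  }
  .relabel_blocks(lab)
}

.relabel_blocks <- function(lab) {
  # relabel in order of first appearance (panel order), 1..L, dropping empties
  f <- factor(lab, levels = unique(lab))
  as.integer(f)
}

#' Per-block LD (genotype correlation) matrices
#'
#' Computes `R_l = X_l' X_l / n_r` for each block, with `X_l` the standardized
#' genotypes of the block's SNPs.
#'
#' @param panel a `genotype_panel`.
#' @param blocks integer block labels from [partition_blocks()].
#' @param s LD regularization parameter in (0, 1]; stored with the block set
#'   and used by the solver, which works with `(1 - s) R_l + s I`.
#' @return An `ld_block_set`: list with `blocks` (list of SNP index vectors),
#'   `R` (list of correlation matrices), `labels`, `s`, `p`, `n_r`, and the
#'   panel `map` for downstream harmonization.
#' @export
block_ld <- function(panel, blocks, s = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"),
            length(blocks) == ncol(panel$genotypes))
  assert_that(s > 0 && s <= 1, "s must be in (0, 1]")
  idx <- split(seq_along(blocks), blocks)
  R <- vector("list", length(idx))
  for (l in seq_along(idx)) {
    x <- standardize_panel(panel, idx[[l]])
    R[[l]] <- crossprod(x) / panel$n_r
  }
  structure(list(blocks = unname(idx), R = R, s = s,
                 p = length(blocks), n_r = panel$n_r,
                 map = panel$map, maf = panel$maf),
            class = "ld_block_set")
}

#' @export
print.ld_block_set <- function(x, ...) {
  sizes <- lengths(x$blocks)
  cat("ld_block_set:", x$p, "SNPs in", length(x$blocks), "blocks",
      sprintf("(sizes %d-%d), s = %g, n_r = %d\n",
              min(sizes), max(sizes), x$s, x$n_r))
  invisible(x)
}

#' Apply the block-diagonal LD operator to per-trait coefficient vectors
#'
#' Computes `R %*% beta` column-wise under the block-diagonal LD model.
#'
#' @param ld an `ld_block_set`.
#' @param beta p x q numeric matrix.
#' @return p x q matrix `R beta`.
#' @export
ld_multiply <- function(ld, beta) {
  stopifnot(inherits(ld, "ld_block_set"))
  beta <- as.matrix(beta)
  assert_that(nrow(beta) == ld$p, "beta rows must match the block set SNP count")
  out <- matrix(0, nrow(beta), ncol(beta))
  for (l in seq_along(ld$blocks)) {
    ii <- ld$blocks[[l]]
    out[ii, ] <- ld$R[[l]] %*% beta[ii, , drop = FALSE]
  }
  dimnames(out) <- dimnames(beta)
  out
}

#' Diagonal of the regularized LD operator term used by the solver
#' @keywords internal
ld_diag <- function(ld) {
  d <- numeric(ld$p)
  for (l in seq_along(ld$blocks)) {
    d[ld$blocks[[l]]] <- diag(ld$R[[l]])
  }
  d
}
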