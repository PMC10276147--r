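## GWAS summary statistics: reading, conversion to SNP-trait correlations,
## harmonization to a reference panel, and pseudo training/validation splits.

#' Read a single-trait GWAS summary-statistics file
#'
#' Reads a headered whitespace/tab-delimited file (gzip accepted) and maps its
#' columns to the canonical names used by the package. Rows missing a
#' mandatory field are dropped with a message.
#'
#' @param path file path.
#' @param column_map named list mapping canonical names to file column names.
#'   Mandatory: `snp`, `a1`, `a2`, and either per-SNP `n` or a global
#'   `n_total`. At least one of \{`beta` + `se`\}, \{`p` + `sign`\}, `z` must
#'   resolve. Optional: `chrom`, `pos`.
#' @param trait_label label for the trait.
#' @param n_total global per-trait sample size used when no per-SNP `n` column
#'   is available (logged).
#' @return data.frame with columns `snp_id`, `a1`, `a2`, `n`, `trait`, the
#'   available association columns, and `chrom`/`pos` when mapped.
#' @export
read_sumstats <- function(path, column_map = list(snp = "SNP", a1 = "A1",
                                                  a2 = "A2", n = "N",
                                                  beta = "BETA", se = "SE"),
                          trait_label = "trait", n_total = NULL) {
  if (!file.exists(path)) stop_input("summary-statistics file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  cols <- names(dt)
  get_col <- function(key) {
    nm <- column_map[[key]]
    if (is.null(nm)) return(NULL)
    if (!nm %in% cols) return(NA)
    dt[[nm]]
  }
  need <- function(key) {
    v <- get_col(key)
    if (is.null(v) || (length(v) == 1L && is.na(v)))
      stop_input("cannot resolve mandatory column '", key, "' via column_map in ", path)
    v
  }
  out <- data.frame(snp_id = as.character(need("snp")),
                    a1 = toupper(as.character(need("a1"))),
                    a2 = toupper(as.character(need("a2"))),
                    stringsAsFactors = FALSE)
  for (key in c("chrom", "pos")) {
    v <- get_col(key)
    if (!is.null(v) && !(length(v) == 1L && is.na(v))) out[[key]] <- v
  }
  nv <- get_col("n")
  if (is.null(nv) || (length(nv) == 1L && is.na(nv))) {
    if (is.null(n_total))
      stop_input("no per-SNP N column and no global n_total given for ", path)
    message("using global N = ", n_total, " for trait ", trait_label)
    out$n <- as.numeric(n_total)
  } else {
    out$n <- as.numeric(nv)
  }
  has <- character(0)
  for (key in c("beta", "se", "p", "sign", "z")) {
    v <- get_col(key)
    if (!is.null(v) && !(length(v) == 1L && is.na(v))) {
      out[[key]] <- as.numeric(v)
      has <- c(has, key)
    }
  }
  if (!(all(c("beta", "se") %in% has) || all(c("p", "sign") %in% has) ||
        "z" %in% has)) {
    stop_input("no usable association columns (beta+se, p+sign, or z) in ", path)
  }
  mand <- c("snp_id", "a1", "a2", "n", intersect(has, c("beta", "se", "p", "sign", "z")))
  ok <- stats::complete.cases(out[, mand])
  if (any(!ok)) {
    message(sum(!ok), " of ", nrow(out), " rows dropped for missing mandatory fields")
    out <- out[ok, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop_input("no rows with complete mandatory fields in ", path)
  if (anyDuplicated(out$snp_id)) {
    warning("duplicated SNP ids in ", path, "; keeping first occurrence",
            call. = FALSE)
    out <- out[!duplicated(out$snp_id), , drop = FALSE]
  }
  out$trait <- trait_label
  rownames(out) <- NULL
  out
}

#' Convert association statistics to SNP-trait correlations
#'
#' Computes `r_j = t_j / sqrt(n_j - 2 + t_j^2)` where `t_j` is the association
#' statistic: `beta/se`, the signed normal quantile of a two-sided p value, or
#' a Z score.
#'
#' @param tab single-trait table from [read_sumstats()].
#' @param mode one of `"beta_se"`, `"p_sign"`, `"z"`.
#' @return the table with an `r` column added.
#' @export
to_correlation <- function(tab, mode = c("beta_se", "p_sign", "z")) {
  mode <- match.arg(mode)
  assert_that(all(tab$n > 2), "per-SNP sample sizes must exceed 2")
  t_stat <- switch(mode,
    beta_se = {
      assert_that(all(c("beta", "se") %in% names(tab)), "beta/se columns required")
      assert_that(all(tab$se > 0), "standard errors must be positive")
      tab$beta / tab$se
    },
    p_sign = {
      assert_that(all(c("p", "sign") %in% names(tab)), "p/sign columns required")
      assert_that(all(tab$p > 0 & tab$p <= 1), "p values must lie in (0, 1]")
      qnorm(tab$p / 2, lower.tail = FALSE) * sign(tab$sign)
    },
    z = {
      assert_that("z" %in% names(tab), "z column required")
      tab$z
    })
  tab$r <- t_stat / sqrt(tab$n - 2 + t_stat^2)
  tab
}

.ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize per-trait summary statistics to a reference panel
#'
#' Intersects SNPs across all traits and the panel by SNP id, aligns effect
#' signs to the panel's counted allele (flipping `r` where the allele pair is
#' swapped), drops SNPs whose alleles do not match the panel, and (by
#' default) drops strand-ambiguous A/T and C/G SNPs. Output SNP order equals
#' panel order.
#'
#' @param traits list of single-trait tables with `r` columns
#'   (see [to_correlation()]).
#' @param ld an `ld_block_set` (carries the panel map) or a `genotype_panel`.
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @return A `summary_statistics` object: list with `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2` (panel alleles), `r` (p x q matrix), `n` (length-q median
#'   per-SNP sample sizes), `trait_names`, and `index` (panel column indices).
#' @export
harmonize_sumstats <- function(traits, ld, drop_ambiguous = TRUE) {
  assert_that(length(traits) >= 1L, "at least one trait table is required")
  map <- if (inherits(ld, "genotype_panel")) ld$map else ld$map
  panel_id <- as.character(map$snp_id)
  keep_id <- panel_id
  if (drop_ambiguous) {
    keep_id <- keep_id[!.ambiguous_pair(toupper(map$a1), toupper(map$a2))]
  }
  for (tt in traits) keep_id <- intersect(keep_id, tt$snp_id)
  if (length(keep_id) == 0L) stop_input("no SNPs shared by all traits and the panel")
  idx <- match(keep_id, panel_id)
  o <- order(idx)
  idx <- idx[o]
  keep_id <- keep_id[o]
  pa1 <- toupper(map$a1[idx]); pa2 <- toupper(map$a2[idx])

  q <- length(traits)
  r <- matrix(NA_real_, length(idx), q)
  n <- numeric(q)
  trait_names <- character(q)
  drop <- logical(length(idx))
  for (k in seq_len(q)) {
    tt <- traits[[k]]
    assert_that("r" %in% names(tt), "run to_correlation() before harmonizing")
    m <- match(keep_id, tt$snp_id)
    ta1 <- tt$a1[m]; ta2 <- tt$a2[m]
    same <- ta1 == pa1 & ta2 == pa2
    swap <- ta1 == pa2 & ta2 == pa1
    drop <- drop | !(same | swap)
    r[, k] <- ifelse(swap, -tt$r[m], tt$r[m])
    n[k] <- stats::median(tt$n[m])
    trait_names[k] <- tt$trait[1] %||% paste0("trait", k)
  }
  if (any(drop)) {
    message(sum(drop), " SNPs dropped for allele mismatch with the panel")
    idx <- idx[!drop]; keep_id <- keep_id[!drop]
    r <- r[!drop, , drop = FALSE]
    pa1 <- pa1[!drop]; pa2 <- pa2[!drop]
  }
  if (length(idx) == 0L) stop_input("no SNPs left after allele matching")
  summary_statistics(snp_id = keep_id, chrom = map$chrom[idx], pos = map$pos[idx],
                     a1 = pa1, a2 = pa2, r = r, n = n,
                     trait_names = trait_names, index = idx)
}

#' Construct a summary_statistics object
#'
#' @param snp_id,chrom,pos,a1,a2 per-SNP identifiers, coordinates and alleles
#'   (a1 = counted allele, aligned to the panel).
#' @param r p x q matrix of SNP-trait correlations, entries in (-1, 1).
#' @param n length-q vector of GWAS sample sizes.
#' @param trait_names length-q labels.
#' @param index panel column indices of the SNPs (or `NULL`).
#' @export
summary_statistics <- function(snp_id, chrom = NA, pos = NA, a1 = NA, a2 = NA,
                               r, n, trait_names = NULL, index = NULL) {
  r <- as.matrix(r)
  assert_that(!anyDuplicated(snp_id), "duplicate SNP ids")
  assert_that(nrow(r) == length(snp_id), "r rows must match snp_id")
  assert_that(all(abs(r) < 1), "|r| must be < 1")
  assert_that(length(n) == ncol(r) && all(n > 0), "n must be positive, one per trait")
  trait_names <- trait_names %||% paste0("trait", seq_len(ncol(r)))
  structure(list(snp_id = as.character(snp_id), chrom = chrom, pos = pos,
                 a1 = a1, a2 = a2, r = r, n = as.numeric(n),
                 trait_names = trait_names, index = index),
            class = "summary_statistics")
}

#' @export
print.summary_statistics <- function(x, ...) {
  cat("summary_statistics:", nrow(x$r), "SNPs x", ncol(x$r), "traits (",
      paste(x$trait_names, collapse = ", "), ")\n")
  cat("  n =", paste(format(x$n, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' Pseudo training/validation split of summary statistics
#'
#' Splits full-sample SNP-trait correlations into pseudo training and
#' validation parts without individual-level data. The training part is
#' perturbed as
#' `rA_k = r_k + sqrt(nB / (nA_k n_k)) * s(r_k) * X_r' g / sqrt(n_r)`
#' with `g` a standard normal vector over the reference subjects and `s(r_k)`
#' the empirical standard deviation of `r_k`; the validation part is the exact
#' complement `rB_k = (n_k r_k - nA_k rA_k) / nB`, so that
#' `nA_k rA_k + nB rB_k = n_k r_k` holds identically.
#'
#' @param ss a `summary_statistics` object.
#' @param panel the reference `genotype_panel` (must contain the SNPs of `ss`).
#' @param nB_fraction validation size as a fraction of the mean GWAS sample
#'   size (default 0.1).
#' @param seed RNG seed.
#' @param shared_g draw one perturbation vector `g` shared by all traits
#'   (default, preserves cross-trait noise structure) or independent per trait.
#' @return A `pseudo_split`: list with `rA`, `rB` (p x q), `nA` (length q),
#'   `nB` (scalar), `seed`, and the parent `ss` metadata.
#' @export
pseudo_split <- function(ss, panel, nB_fraction = 0.1, seed = NULL,
                         shared_g = TRUE) {
  stopifnot(inherits(ss, "summary_statistics"), inherits(panel, "genotype_panel"))
  nB <- round(nB_fraction * mean(ss$n))
  assert_that(nB > 0 && all(nB < ss$n), "nB must be positive and below every n_k")
  nA <- ss$n - nB
  local_seed(seed)
  idx <- ss$index %||% match(ss$snp_id, panel$map$snp_id)
  assert_that(!anyNA(idx), "panel does not contain all summary-statistic SNPs")
  X <- standardize_panel(panel, idx)
  n_r <- panel$n_r
  q <- ncol(ss$r)
  rA <- matrix(NA_real_, nrow(ss$r), q)
  g <- rnorm(n_r)
  for (k in seq_len(q)) {
    if (!shared_g && k > 1L) g <- rnorm(n_r)
    noise <- crossprod(X, g) / sqrt(n_r)
    scale_k <- sqrt(nB / (nA[k] * ss$n[k])) * sd(ss$r[, k])
    rA[, k] <- ss$r[, k] + scale_k * as.numeric(noise)
  }
  rB <- sweep(sweep(ss$r, 2L, ss$n, "*") - sweep(rA, 2L, nA, "*"), 2L, nB, "/")
  structure(list(rA = rA, rB = rB, nA = nA, nB = nB, seed = seed,
                 snp_id = ss$snp_id, index = idx, n = ss$n,
                 trait_names = ss$trait_names),
            class = "pseudo_split")
}

#' Training-part summary statistics of a pseudo split
#'
#' @param split a `pseudo_split`.
#' @return a `summary_statistics` object with `r = rA`, `n = nA`. Entries of
#'   `rA` falling outside (-1, 1) (possible only in pathological splits) are
#'   clipped with a warning.
#' @export
training_sumstats <- function(split) {
  stopifnot(inherits(split, "pseudo_split"))
  rA <- split$rA
  if (any(abs(rA) >= 1)) {
    warning("pseudo-training correlations outside (-1, 1) clipped", call. = FALSE)
    rA <- pmin(pmax(rA, -1 + 1e-12), 1 - 1e-12)
  }
  summary_statistics(snp_id = split$snp_id, r = rA, n = split$nA,
                     trait_names = split$trait_names, index = split$index)
}

#' Serialize a pseudo split as two TSVs plus a JSON sidecar
#'
#' @param split a `pseudo_split`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pseudo_split <- function(split, dir) {
  stopifnot(inherits(split, "pseudo_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ra <- data.table::data.table(snp_id = split$snp_id, split$rA)
  rb <- data.table::data.table(snp_id = split$snp_id, split$rB)
  data.table::setnames(ra, c("snp_id", split$trait_names))
  data.table::setnames(rb, c("snp_id", split$trait_names))
  data.table::fwrite(ra, file.path(dir, "rA.tsv"), sep = "\t")
  data.table::fwrite(rb, file.path(dir, "rB.tsv"), sep = "\t")
  jsonlite::write_json(list(nA = split$nA, nB = split$nB, seed = split$seed,
                            n = split$n, trait_names = split$trait_names),
                       file.path(dir, "pseudo_split.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
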