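## PLINK 1 binary (bed/bim/fam) input/output.
##
## The .bed file is SNP-major: a 3-byte magic (0x6c 0x1b 0x01) followed by
## ceiling(n/4) bytes per SNP, two bits per subject starting at the low bits:
##   00 = homozygous A1, 10 = heterozygous, 11 = homozygous A2, 01 = missing.
## Genotypes are returned as counts of the A1 allele (0/1/2, NA = missing).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset into a genotype panel
#'
#' Reads a `.bed`/`.bim`/`.fam` triple, applies per-SNP quality control
#' (missing-rate and minor-allele-frequency filters), imputes the remaining
#' missing genotypes by the per-SNP mode, and recodes counted alleles so that
#' the counted allele is always the panel minor allele.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @param max_missing Maximum per-SNP genotype missing rate; SNPs above the
#'   threshold are removed (default 0.01).
#' @param min_maf Minimum minor-allele frequency; SNPs below the threshold
#'   (including monomorphic SNPs) are removed (default 0.001).
#' @return A `genotype_panel` object: list with `genotypes` (n_r x p integer
#'   matrix of minor-allele counts), `maf`, `n_r`, and `map` (data.frame with
#'   `chrom`, `snp_id`, `pos`, `a1` counted/minor allele, `a2`).
#' @export
read_plink <- function(prefix, max_missing = 0.01, min_maf = 0.001) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_input("PLINK file not found: ", f)
  }
  map <- data.table::fread(bim, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)))
  fam_dt <- data.table::fread(fam, header = FALSE)
  n <- nrow(fam_dt)
  p <- nrow(map)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic)) {
    stop_input("not a PLINK 1 bed file (bad magic bytes): ", bed)
  }
  bps <- ceiling(n / 4)
  if (length(raw) != 3L + bps * p) {
    stop_input("bed file size inconsistent with bim/fam dimensions: ", bed)
  }
  body <- raw[-(1:3)]
  # decode two-bit fields; lookup by code value 0..3
  codes <- matrix(0L, nrow = 4 * bps, ncol = p)
  ints <- as.integer(body)
  dim(ints) <- c(bps, p)
  for (shift in 0:3) {
    codes[seq.int(shift + 1L, by = 4L, length.out = bps), ] <-
      bitwAnd(bitwShiftR(ints, 2L * shift), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # code -> A1 count: 0 -> 2, 2 -> 1, 3 -> 0, 1 -> NA
  lut <- c(2L, NA_integer_, 1L, 0L)
  geno <- matrix(lut[codes + 1L], nrow = n, ncol = p)

  miss_rate <- colMeans(is.na(geno))
  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- miss_rate <= max_missing & maf >= min_maf & maf > 0 & !is.nan(freq)
  if (!any(keep)) stop_input("no SNPs left after quality control")
  geno <- geno[, keep, drop = FALSE]
  map <- as.data.frame(map[keep, c("chrom", "snp_id", "pos", "a1", "a2")])
  genotype_panel(geno, map, impute = TRUE)
}

#' Construct a genotype panel from a matrix of allele counts
#'
#' @param genotypes n_r x p matrix of allele counts in 0/1/2 (NA allowed when
#'   `impute = TRUE`).
#' @param map data.frame with columns `chrom`, `snp_id`, `pos`, `a1`, `a2`
#'   where `a1` is the counted allele.
#' @param impute impute missing genotypes by the per-SNP mode.
#' @return A `genotype_panel` with the counted allele recoded to the panel
#'   minor allele where needed.
#' @export
genotype_panel <- function(genotypes, map, impute = FALSE) {
  stopifnot(is.matrix(genotypes), nrow(map) == ncol(genotypes))
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes)) {
    if (!impute) stop_input("missing genotypes present; set impute = TRUE")
    for (j in which(colSums(is.na(genotypes)) > 0L)) {
      g <- genotypes[, j]
      tab <- tabulate(g + 1L, nbins = 3L)
      genotypes[is.na(g), j] <- which.max(tab) - 1L
    }
  }
  freq <- colMeans(genotypes) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip]
    tmp <- map$a1[flip]
    map$a1[flip] <- map$a2[flip]
    map$a2[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  if (any(freq == 0)) stop_input("monomorphic SNPs present; filter them first")
  structure(list(genotypes = genotypes,
                 map = map,
                 maf = freq,
                 n_r = nrow(genotypes)),
            class = "genotype_panel")
}

#' Standardized genotype matrix of a panel
#'
#' Columns are centered at twice the empirical allele frequency and scaled by
#' `sqrt(2 p (1 - p))`, the variance of an allele count under
#' Hardy-Weinberg equilibrium. Column means are exactly 0; column variances
#' are approximately (not exactly) 1.
#'
#' @param panel a `genotype_panel`.
#' @param cols optional column (SNP) subset.
#' @return numeric matrix n_r x length(cols).
#' @export
standardize_panel <- function(panel, cols = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- if (is.null(cols)) panel$genotypes else panel$genotypes[, cols, drop = FALSE]
  p <- if (is.null(cols)) panel$maf else panel$maf[cols]
  .standardize_geno(g, p)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", x$n_r, "subjects x", ncol(x$genotypes), "SNPs\n")
  cat("  MAF range:", sprintf("%.4f - %.4f", min(x$maf), max(x$maf)), "\n")
  invisible(x)
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix for `.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  n <- nrow(g); p <- ncol(g)
  # A1 count -> code: 2 -> 0, 1 -> 2, 0 -> 3
  code_lut <- c(3L, 2L, 0L)
  bps <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bps, ncol = p)
  codes[seq_len(n), ] <- code_lut[g + 1L]
  packed <- codes[seq.int(1L, by = 4L, length.out = bps), , drop = FALSE] +
    bitwShiftL(codes[seq.int(2L, by = 4L, length.out = bps), , drop = FALSE], 2L) +
    bitwShiftL(codes[seq.int(3L, by = 4L, length.out = bps), , drop = FALSE], 4L) +
    bitwShiftL(codes[seq.int(4L, by = 4L, length.out = bps), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(packed), con)

  m <- panel$map
  data.table::fwrite(data.table::data.table(m$chrom, m$snp_id, 0L, m$pos, m$a1, m$a2),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  fam <- data.table::data.table(paste0("F", seq_len(n)), paste0("I", seq_len(n)),
                                0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  invisible(prefix)
}
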