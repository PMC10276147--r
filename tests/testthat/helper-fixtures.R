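# Shared fixture builders and the independent convex-minimizer oracle.

# Small panel + LD blocks + constant covariance model + simulated sumstats,
# built once per test file as needed.
tiny_setup <- function(n = 300, p = 120, block_size = 20, seed = 11,
                       n_gwas = c(20000, 20000), scen = simulation_scenario()) {
  fx <- make_fixture_panel(n, p, block_size = block_size, seed = seed)
  status <- assign_causal_status(scen, p, seed = seed + 1)
  eff <- draw_effects(status, scen, seed = seed + 2)
  ss <- draw_region_sumstats(eff, fx$ld, n = n_gwas, seed = seed + 3)
  model <- constant_covariance_model(matrix(c(0.47, 0.27, 0.27, 0.45), 2), p)
  list(fx = fx, eff = eff, ss = ss, model = model, scen = scen)
}

# Dense quadratic form of the solver objective:
#   f(beta) = beta' H beta - 2 b' beta + 2 lambda |W beta|_1
# built by brute force from the same inputs the solver sees. Coefficient
# order is trait-within-SNP: idx(j, k) = (j - 1) q + k.
dense_system <- function(ss, ld, model, s = ld$s, cross_term_factor = 1) {
  p <- ld$p; q <- ncol(ss$r)
  Rd <- matrix(0, p, p)
  for (l in seq_along(ld$blocks)) {
    ii <- ld$blocks[[l]]
    Rd[ii, ii] <- ld$R[[l]]
  }
  nsig <- ss$n / model$residual
  H <- matrix(0, p * q, p * q)
  b <- numeric(p * q)
  idx <- function(j, k) (j - 1L) * q + k
  for (k in seq_len(q)) {
    kk <- idx(seq_len(p), k)
    H[kk, kk] <- nsig[k] * ((1 - s) * Rd + s * diag(p))
    b[kk] <- nsig[k] * ss$r[, k]
  }
  for (j in seq_len(p)) {
    P <- model$precision[, , j]
    Q <- diag(diag(P), q) + cross_term_factor * (P - diag(diag(P), q))
    jj <- idx(j, seq_len(q))
    H[jj, jj] <- H[jj, jj] + Q
  }
  list(H = H, b = b, p = p, q = q)
}

# Independent proximal-gradient (FISTA) minimizer of the explicit objective.
# Deliberately generic: it knows nothing about coordinate descent, LD blocks
# or soft-threshold updates beyond the L1 prox.
prox_grad_minimize <- function(H, b, lambda, w, iters = 20000L) {
  L <- 2 * max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  thr <- step * 2 * lambda * w
  x <- numeric(length(b))
  y <- x
  t_acc <- 1
  for (it in seq_len(iters)) {
    g <- 2 * (H %*% y - b)
    z <- as.numeric(y - step * g)
    xn <- sign(z) * pmax(abs(z) - thr, 0)
    xn[is.infinite(w)] <- 0
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- xn + (t_acc - 1) / t_new * (xn - x)
    x <- xn
    t_acc <- t_new
  }
  x
}

# Reshape a stacked trait-within-SNP vector to a p x q matrix.
unstack_beta <- function(x, p, q) matrix(x, nrow = p, ncol = q, byrow = TRUE)

# Write a small sumstats TSV and return its path.
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}
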