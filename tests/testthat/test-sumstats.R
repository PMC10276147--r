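test_that("read_sumstats validates columns and drops incomplete rows", {
  df <- data.frame(SNP = paste0("rs", 1:10), A1 = "A", A2 = "G",
                   BETA = rnorm(10), SE = runif(10, 0.01, 0.05), N = 1000L)
  path <- write_sumstats_file(df)
  tab <- read_sumstats(path, trait_label = "t1")
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$snp_id, df$SNP)
  expect_equal(tab$beta, df$BETA)

  # missing allele columns -> configuration error
  path2 <- write_sumstats_file(df[, c("SNP", "BETA", "SE", "N")])
  expect_error(read_sumstats(path2), "a1")

  # 3 of 10 rows lacking N -> 7 rows survive, with a message
  df3 <- df
  df3$N[c(2, 5, 9)] <- NA
  path3 <- write_sumstats_file(df3)
  expect_message(tab3 <- read_sumstats(path3), "3 of 10 rows dropped")
  expect_equal(nrow(tab3), 7L)

  # all rows incomplete -> input error
  df4 <- df
  df4$SE <- NA
  expect_error(read_sumstats(write_sumstats_file(df4)), "no rows")

  # global N fallback logs
  expect_message(
    tab5 <- read_sumstats(write_sumstats_file(df[, c("SNP", "A1", "A2", "BETA", "SE")]),
                          n_total = 5000),
    "global N")
  expect_true(all(tab5$n == 5000))

  # duplicated ids: first kept with a warning
  df6 <- rbind(df, df[1, ])
  expect_warning(tab6 <- read_sumstats(write_sumstats_file(df6)), "duplicated")
  expect_equal(nrow(tab6), 10L)
})

test_that("to_correlation matches the closed form in all three modes", {
  # beta/se: t = 2, n = 10000 -> r = 2 / sqrt(9998 + 4)
  tab <- data.frame(snp_id = "a", beta = 0.1, se = 0.05, n = 10000)
  expect_equal(to_correlation(tab, "beta_se")$r, 2 / sqrt(10002))

  # p = 1 gives a zero statistic hence r = 0
  tab <- data.frame(snp_id = "a", p = 1, sign = 1, n = 1000)
  expect_equal(to_correlation(tab, "p_sign")$r, 0)

  # two-sided p = 0.05 -> t = qnorm(0.975)
  tab <- data.frame(snp_id = "a", p = 0.05, sign = 1, n = 10000)
  t_or <- qnorm(0.975)
  expect_equal(to_correlation(tab, "p_sign")$r, t_or / sqrt(9998 + t_or^2))

  # z mode passthrough of the statistic
  tab <- data.frame(snp_id = "a", z = -1.5, n = 50)
  expect_equal(to_correlation(tab, "z")$r, -1.5 / sqrt(48 + 2.25))

  # errors: invalid p, tiny n
  expect_error(to_correlation(data.frame(snp_id = "a", p = 0, sign = 1, n = 10),
                              "p_sign"), "p values")
  expect_error(to_correlation(data.frame(snp_id = "a", z = 1, n = 2), "z"),
               "exceed 2")
})

test_that("to_correlation is sign-equivariant", {
  set.seed(4)
  tab <- data.frame(snp_id = paste0("s", 1:50), beta = rnorm(50),
                    se = runif(50, 0.01, 0.1), n = 10000)
  neg <- tab
  neg$beta <- -neg$beta
  expect_identical(to_correlation(tab, "beta_se")$r,
                   -to_correlation(neg, "beta_se")$r)
})

test_that("harmonize_sumstats aligns alleles, drops ambiguous SNPs, is idempotent", {
  fx <- make_fixture_panel(100, 10, block_size = 5, seed = 3)
  map <- fx$panel$map # counted allele a1, other a2
  mk_trait <- function(ids, a1, a2, r, label) {
    data.frame(snp_id = ids, a1 = a1, a2 = a2, n = 1000, r = r,
               trait = label, stringsAsFactors = FALSE)
  }
  # trait 1: swapped alleles on SNP 1 -> r flipped
  t1 <- mk_trait(map$snp_id, map$a1, map$a2, rep(0.01, 10), "t1")
  t1$a1[1] <- map$a2[1]; t1$a2[1] <- map$a1[1]
  # trait 2: shares only 8 of 10 SNPs
  t2 <- mk_trait(map$snp_id[1:8], map$a1[1:8], map$a2[1:8], rep(0.02, 8), "t2")
  ss <- harmonize_sumstats(list(t1, t2), fx$ld)
  expect_equal(nrow(ss$r), 8L)
  expect_equal(ss$snp_id, map$snp_id[1:8]) # panel order
  expect_equal(ss$r[1, 1], -0.01)          # flipped under allele swap
  expect_equal(ss$r[2:8, 1], rep(0.01, 7))

  # ambiguous A/T SNP dropped by default, kept when disabled
  t3 <- mk_trait(map$snp_id, map$a1, map$a2, rep(0.01, 10), "t3")
  fx2 <- fx
  fx2$ld$map$a1[2] <- "A"; fx2$ld$map$a2[2] <- "T"
  t3$a1[2] <- "A"; t3$a2[2] <- "T"
  ss3 <- harmonize_sumstats(list(t3), fx2$ld)
  expect_false("snp2" %in% ss3$snp_id)
  ss3b <- harmonize_sumstats(list(t3), fx2$ld, drop_ambiguous = FALSE)
  expect_true("snp2" %in% ss3b$snp_id)

  # idempotence: rebuilding trait tables from the harmonized output and
  # re-harmonizing reproduces it exactly
  again <- lapply(1:2, function(k) {
    mk_trait(ss$snp_id, ss$a1, ss$a2, ss$r[, k], ss$trait_names[k])
  })
  for (k in 1:2) again[[k]]$n <- ss$n[k]
  ss_again <- harmonize_sumstats(again, fx$ld)
  expect_equal(ss_again$r, ss$r)
  expect_equal(ss_again$snp_id, ss$snp_id)

  # empty intersection errors
  t_off <- mk_trait(paste0("x", 1:5), "A", "G", rep(0.01, 5), "t")
  expect_error(harmonize_sumstats(list(t_off), fx$ld), "no SNPs")
})

test_that("pseudo_split sizes follow the 10%-of-mean rule and errors when nB too large", {
  fx <- make_fixture_panel(200, 50, block_size = 25, seed = 5)
  r <- matrix(runif(100, -0.02, 0.02), 50, 2)
  ss <- summary_statistics(snp_id = fx$panel$map$snp_id, r = r,
                           n = c(1e5, 3e5), index = 1:50)
  sp <- pseudo_split(ss, fx$panel, nB_fraction = 0.1, seed = 1)
  expect_equal(sp$nB, 20000)
  expect_equal(sp$nA, c(80000, 280000))
  ss_bad <- summary_statistics(snp_id = fx$panel$map$snp_id, r = r,
                               n = c(1e4, 3e5), index = 1:50)
  expect_error(pseudo_split(ss_bad, fx$panel, nB_fraction = 0.1), "below every")
})

test_that("pseudo_split recombines exactly and is reproducible under seed", {
  fx <- make_fixture_panel(300, 50, block_size = 25, seed = 6)
  set.seed(2)
  r <- matrix(runif(100, -0.02, 0.02), 50, 2)
  ss <- summary_statistics(snp_id = fx$panel$map$snp_id, r = r,
                           n = c(1e5, 2e5), index = 1:50)
  sp1 <- pseudo_split(ss, fx$panel, seed = 7)
  sp2 <- pseudo_split(ss, fx$panel, seed = 7)
  expect_identical(sp1$rA, sp2$rA)
  lhs <- sweep(sp1$rA, 2, sp1$nA, "*") + sp1$nB * sp1$rB
  rhs <- sweep(ss$r, 2, ss$n, "*")
  expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1)), 1e-12)
  # different seed, different draw
  expect_false(identical(sp1$rA, pseudo_split(ss, fx$panel, seed = 8)$rA))
})

test_that("pseudo_split serialization writes both parts and the sidecar", {
  fx <- make_fixture_panel(100, 20, block_size = 10, seed = 9)
  r <- matrix(runif(40, -0.02, 0.02), 20, 2)
  ss <- summary_statistics(snp_id = fx$panel$map$snp_id, r = r,
                           n = c(5e4, 5e4), index = 1:20)
  sp <- pseudo_split(ss, fx$panel, seed = 3)
  dir <- tempfile()
  write_pseudo_split(sp, dir)
  expect_true(all(file.exists(file.path(dir, c("rA.tsv", "rB.tsv",
                                               "pseudo_split.json")))))
  side <- jsonlite::read_json(file.path(dir, "pseudo_split.json"))
  expect_equal(side$nB, sp$nB)
  ra <- data.table::fread(file.path(dir, "rA.tsv"))
  expect_equal(as.matrix(ra[, -1]), sp$rA, ignore_attr = TRUE)
})
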