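mk_region <- function(beta, se, ids = paste0("snp_", seq_along(beta)), ...) {
  region_panel(ids, beta, rep_len(se, length(beta)), ...)
}

test_that("the SMR statistic follows its closed form", {
  # z_eqtl = 10, z_gwas = 4: T = 1600/116, p from the chi-square(1) tail
  eq <- mk_region(beta = c(0.5, 0.01), se = 0.05) # top z = 10
  gw <- mk_region(beta = c(0.2, 0.01), se = 0.05) # z = 4 at the top SNP
  s <- smr_test(eq, gw)
  expect_equal(s$top_snp, "snp_1")
  expect_equal(s$z_eqtl, 10)
  expect_equal(s$z_gwas, 4)
  t_expect <- 1600 / 116
  expect_equal(s$z_gwas^2 * s$z_eqtl^2 / (s$z_gwas^2 + s$z_eqtl^2), t_expect)
  expect_equal(s$p_smr, pchisq(t_expect, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(s$b_xy, 0.2 / 0.5)
  expect_equal(s$se_xy, abs(s$b_xy) / sqrt(t_expect))

  # null GWAS signal at the top SNP: T = 0, p = 1
  gw0 <- mk_region(beta = c(0, 0.01), se = 0.05)
  s0 <- smr_test(eq, gw0)
  expect_equal(s0$p_smr, 1)

  # b_xy ratio example
  eq2 <- mk_region(beta = 0.5, se = 0.05)
  gw2 <- mk_region(beta = 0.05, se = 0.05)
  expect_equal(smr_test(eq2, gw2)$b_xy, 0.1)

  # no genome-wide significant eQTL -> skipped with reason
  weak <- mk_region(beta = 0.1, se = 0.05) # z = 2
  expect_equal(smr_test(weak, gw2)$status, "no valid instrument")
})

test_that("p_smr is invariant to common rescaling and obeys the min-z limit", {
  eq <- mk_region(beta = c(0.5, 0.01), se = 0.05)
  gw <- mk_region(beta = c(0.2, 0.01), se = 0.05)
  p0 <- smr_test(eq, gw)$p_smr
  for (f in c(0.1, 3, 42)) {
    eq_s <- mk_region(beta = c(0.5, 0.01) * f, se = 0.05 * f)
    expect_equal(smr_test(eq_s, gw)$p_smr, p0, tolerance = 1e-12)
  }
  # as the larger |z| grows, T tends to the smaller z^2
  gw_fix <- mk_region(beta = c(0.2, 0.001), se = 0.05) # z_gwas = 4
  for (z_big in c(50, 200, 1000)) {
    eq_big <- mk_region(beta = c(z_big * 0.05, 0.001), se = 0.05)
    t_val <- with(smr_test(eq_big, gw_fix), z_gwas^2 * z_eqtl^2 / (z_gwas^2 + z_eqtl^2))
    expect_lt(abs(t_val - 16), 16 * 20 / z_big^2)
  }
})

test_that("HEIDI SNP selection respects p, r2 and cap rules", {
  m <- 30
  ld <- simulate_ld(m, 0.9)
  z <- c(12, rep(6, m - 1)) # snp_1 is the top
  eq <- region_panel(rownames(ld), z / sqrt(1e4), rep(1 / sqrt(1e4), m))
  sel <- select_heidi_snps(eq, ld)
  expect_equal(sel[1], "snp_1")
  r2 <- ld[sel[-1], "snp_1"]^2
  expect_true(all(r2 >= 0.05 & r2 <= 0.9))
  expect_lte(length(sel), 20)

  expect_true("snp_2" %in% sel) # r = 0.9 -> r2 = 0.81, inside the band
  # with rho = 0.995 the first neighbours exceed r2_max and drop out
  ld2 <- simulate_ld(m, 0.995)
  eq2 <- region_panel(rownames(ld2), z / sqrt(1e4), rep(1 / sqrt(1e4), m))
  sel2 <- select_heidi_snps(eq2, ld2)
  expect_false("snp_2" %in% sel2) # r2 = 0.99 > 0.9
  # insignificant eQTLs never enter
  z3 <- c(12, rep(1, m - 1))
  eq3 <- region_panel(rownames(ld), z3 / sqrt(1e4), rep(1 / sqrt(1e4), m))
  expect_equal(select_heidi_snps(eq3, ld), "snp_1")
})

test_that("the weighted-chi-square tail matches closed forms and Monte Carlo", {
  # single weight: exactly chi-square(1)
  expect_equal(
    weighted_chisq_pvalue(3.84, 1),
    pchisq(3.84, 1, lower.tail = FALSE),
    tolerance = 1e-6
  )
  # equal weights: exactly chi-square(k)
  expect_equal(
    weighted_chisq_pvalue(11.07, rep(1, 5)),
    pchisq(11.07, 5, lower.tail = FALSE),
    tolerance = 1e-6
  )
  # unequal weights: Monte-Carlo oracle
  lambda <- c(2.5, 1.2, 0.6, 0.3)
  withr::local_seed(17)
  draws <- colSums(lambda * matrix(rnorm(4 * 2e5)^2, nrow = 4))
  q <- 12
  expect_lt(abs(weighted_chisq_pvalue(q, lambda) - mean(draws > q)), 0.01)
  # Satterthwaite fallback is a sane approximation of the same tail
  expect_lt(
    abs(weighted_chisq_pvalue(q, lambda, method = "satterthwaite") - mean(draws > q)),
    0.02
  )
})

test_that("HEIDI is null for noise-free shared-variant data and discriminates", {
  m <- 60
  ld <- simulate_ld(m, 0.9)
  n <- 3e4
  # noiseless single-causal region: b_xy identical across SNPs -> T = 0, p = 1
  causal <- 30
  joint <- numeric(m)
  joint[causal] <- 12 / sqrt(n)
  marg <- drop(unclass(ld) %*% joint)
  eq <- region_panel(rownames(ld), marg, rep(1 / sqrt(n), m))
  gw <- region_panel(rownames(ld), 0.7 * marg, rep(1 / sqrt(n), m))
  h <- heidi_test(eq, gw, ld)
  expect_equal(h$t_heidi, 0, tolerance = 1e-16)
  expect_equal(h$p_heidi, 1)
  expect_gte(h$n_heidi_snps, 3)

  # fewer than 3 eligible SNPs: p not computed
  tiny <- simulate_ld(2, 0.5)
  eq_t <- region_panel(rownames(tiny), c(0.5, 0.01), c(0.05, 0.05))
  gw_t <- region_panel(rownames(tiny), c(0.2, 0.01), c(0.05, 0.05))
  h_t <- heidi_test(eq_t, gw_t, tiny)
  expect_true(is.na(h_t$p_heidi))

  # linkage scenario at strong effects: small p in a typical replicate
  cfg <- region_scenario_config(
    n_snps = 100, ld_rho = 0.9,
    architecture = "distinct_variants", effect_sizes = c(12, 10), seed = 8
  )
  pr <- simulate_region_pair(cfg)
  h_link <- heidi_test(pr$panel1, pr$panel2, pr$ld)
  expect_lt(h_link$p_heidi, 0.05)
})
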