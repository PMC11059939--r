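test_that("Wald ratio implements the delta-method closed form", {
  est <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.5)
  expect_equal(est$ci_low, 2.0 - 1.96 * 0.5)

  null_y <- wald_ratio(0.1, 0.02, 0, 0.05)
  expect_equal(null_y$beta, 0)
  expect_equal(null_y$pval, 1)

  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "null instrument")
})

test_that("IVW matches the hand-computed two-instrument oracle exactly", {
  set <- two_instrument_set()
  fixed <- ivw(set, mode = "fixed")
  expect_equal(fixed$beta, 1.6, tolerance = 1e-12)
  expect_equal(fixed$se, 1 / sqrt(5), tolerance = 1e-12)

  # multiplicative random effects: Q = 0.2 on 1 df < 1, scale floored at 1
  rand <- ivw(set)
  expect_equal(rand$se, fixed$se)

  # single instrument reduces to the Wald ratio exactly
  one <- harmonized_set(0.1, 0.02, 0.2, 0.05)
  expect_equal(ivw(one)$beta, wald_ratio(0.1, 0.02, 0.2, 0.05)$beta)
  expect_equal(ivw(one)$se, wald_ratio(0.1, 0.02, 0.2, 0.05)$se)

  # identical ratios: estimate equals the ratio, random se equals fixed se
  line <- exact_line_set(slope = 1.5)
  expect_equal(ivw(line)$beta, 1.5, tolerance = 1e-12)
  expect_equal(ivw(line)$se, ivw(line, "fixed")$se)

  expect_error(ivw(harmonized_set(numeric(0), numeric(0), numeric(0), numeric(0))))
})

test_that("IVW is invariant under reordering and joint sign flips", {
  withr::local_seed(7)
  k <- 15
  set <- harmonized_set(
    rnorm(k, 0.1, 0.03), rep(0.01, k),
    rnorm(k, 0.15, 0.05), runif(k, 0.02, 0.08)
  )
  b0 <- ivw(set, "fixed")$beta
  perm <- sample(k)
  set_perm <- harmonized_set(
    set$instruments$beta_exposure[perm], set$instruments$se_exposure[perm],
    set$instruments$beta_outcome[perm], set$instruments$se_outcome[perm]
  )
  expect_equal(ivw(set_perm, "fixed")$beta, b0, tolerance = 1e-12)

  flip <- rep(1, k)
  flip[c(2, 5, 9)] <- -1
  set_flip <- harmonized_set(
    set$instruments$beta_exposure * flip, set$instruments$se_exposure,
    set$instruments$beta_outcome * flip, set$instruments$se_outcome
  )
  expect_equal(ivw(set_flip, "fixed")$beta, b0, tolerance = 1e-12)
})

test_that("MR-Egger matches a weighted-least-squares oracle", {
  # data exactly on a line through the origin: intercept 0, slope = IVW
  line <- exact_line_set(slope = 2)
  eg <- mr_egger(line)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-10)
  expect_equal(eg$slope$beta, ivw(line, "fixed")$beta, tolerance = 1e-10)

  # constant pleiotropic shift is recovered as the intercept
  bx <- seq(0.05, 0.3, length.out = 8)
  by <- 1.2 * bx + 0.05
  shift <- harmonized_set(bx, rep(0.01, 8), by, seq(0.03, 0.08, length.out = 8))
  eg2 <- mr_egger(shift)
  expect_equal(eg2$intercept$beta, 0.05, tolerance = 1e-10)
  expect_equal(eg2$slope$beta, 1.2, tolerance = 1e-10)

  # independent WLS oracle on noisy data
  withr::local_seed(11)
  by_noisy <- 1.2 * bx + 0.05 + rnorm(8, 0, 0.02)
  noisy <- harmonized_set(bx, rep(0.01, 8), by_noisy, seq(0.03, 0.08, length.out = 8))
  fit <- stats::lm(by_noisy ~ bx, weights = 1 / noisy$instruments$se_outcome^2)
  eg3 <- mr_egger(noisy)
  expect_equal(unname(eg3$intercept$beta), unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(unname(eg3$slope$beta), unname(coef(fit)[2]), tolerance = 1e-10)

  expect_error(mr_egger(two_instrument_set()), "at least 3")
})

test_that("weighted median equals the unweighted median at equal weights", {
  # equal weights, one wild outlier ratio
  set <- harmonized_set(
    rep(0.1, 3), rep(0.01, 3),
    c(0.1, 0.2, 10), rep(0.05, 3)
  )
  est <- weighted_median(set, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2) # median of ratios {1, 2, 100}

  withr::local_seed(3)
  for (k in c(5, 6)) { # odd and even
    bx <- rep(0.1, k)
    by <- rnorm(k, 0.15, 0.05)
    s <- harmonized_set(bx, rep(0.01, k), by, rep(0.05, k))
    expect_equal(
      weighted_median(s, n_boot = 50, seed = 1)$beta,
      median(by / bx)
    )
  }

  # an instrument carrying >50% of total weight dictates the estimate
  dom <- harmonized_set(
    c(1, 0.05, 0.05), rep(0.01, 3),
    c(3, 0.05, 0.05), rep(0.05, 3)
  )
  expect_equal(weighted_median(dom, n_boot = 50, seed = 1)$beta, 3, tolerance = 0.01)

  expect_error(weighted_median(two_instrument_set()), "at least 3")
})

test_that("bootstrap standard errors are reproducible bit-for-bit by seed", {
  set <- harmonized_set(
    seq(0.05, 0.3, length.out = 6), rep(0.01, 6),
    seq(0.08, 0.5, length.out = 6), rep(0.05, 6)
  )
  a <- weighted_median(set, n_boot = 200, seed = 99)
  b <- weighted_median(set, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- weighted_median(set, n_boot = 200, seed = 100)
  expect_false(identical(a$se, c$se))

  m1 <- mode_estimate(set, "weighted", n_boot = 200, seed = 99)
  m2 <- mode_estimate(set, "weighted", n_boot = 200, seed = 99)
  expect_identical(m1$se, m2$se)
})

test_that("mode estimators locate the dominant ratio cluster", {
  # ratios {2, 2, 2, 5}: mode at the cluster
  set <- harmonized_set(
    rep(0.1, 4), rep(0.01, 4),
    c(0.2, 0.2, 0.2, 0.5), rep(0.05, 4)
  )
  est <- mode_estimate(set, "simple", n_boot = 50, seed = 1)
  expect_lt(abs(est$beta - 2), 0.35)

  # degenerate: all ratios identical -> that ratio exactly
  same <- harmonized_set(rep(0.1, 4), rep(0.01, 4), rep(0.25, 4), rep(0.05, 4))
  expect_equal(mode_estimate(same, "simple", n_boot = 50, seed = 1)$beta, 2.5)

  # two clusters, 6 SNPs near 1.0 vs 3 near 3.0 -> estimate near 1.0,
  # cross-checked against a direct kernel-density oracle on the same grid
  withr::local_seed(21)
  ratios <- c(rnorm(6, 1, 0.05), rnorm(3, 3, 0.05))
  bx <- rep(0.1, 9)
  clus <- harmonized_set(bx, rep(0.01, 9), ratios * bx, rep(0.05, 9))
  est2 <- mode_estimate(clus, "simple", n_boot = 50, seed = 1)
  h <- 0.9 * min(sd(ratios), IQR(ratios) / 1.349) * 9^(-1 / 5)
  dd <- density(ratios, bw = h, n = 512, from = min(ratios) - 3 * h, to = max(ratios) + 3 * h)
  expect_equal(est2$beta, dd$x[which.max(dd$y)])
  expect_lt(abs(est2$beta - 1), 0.3)

  expect_error(mode_estimate(two_instrument_set()), "at least 3")
})
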