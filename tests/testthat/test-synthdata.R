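test_that("harmonic generator carries the analytic truth", {
  sched <- lambda_schedule(5)
  sym <- sample_harmonic_alchemy(sched, 2, 2, 300, n_samples = 10,
                                 n_replicas = 1, seed = 1)
  expect_equal(attr(sym$dhdl, "truth"), 0)
  sim <- sample_harmonic_alchemy(sched, 1, 4, 300, n_samples = 10,
                                 n_replicas = 2, seed = 1)
  expect_equal(attr(sim$dhdl, "truth"), harmonic_truth(), tolerance = 1e-12)
  expect_equal(sim$u_kn[[1]]$truth, harmonic_truth(), tolerance = 1e-12)
  # truth matches independent numerical quadrature of the exact TI
  # integrand kT(k1-k0)/(2 k_lambda)
  kt <- 1.9872e-3 * 300
  quad <- integrate(function(l) kt * 3 / (2 * (1 + 3 * l)), 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(attr(sim$dhdl, "truth"), quad, tolerance = 1e-10)
})

test_that("harmonic window means and variances match Gaussian theory", {
  sched <- lambda_schedule(7)
  kt <- 1.9872e-3 * 300
  sim <- sample_harmonic_alchemy(sched, 1, 4, 300, n_samples = 4000,
                                 n_replicas = 1, seed = 7)
  d <- sim$dhdl
  for (w in unique(d$window)) {
    s <- d$dhdl_kcal_mol[d$window == w]
    lam <- d$lambda[d$window == w][1]
    klam <- (1 - lam) * 1 + lam * 4
    expected <- kt * 3 / (2 * klam)
    sem <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - expected), 4 * sem)
    # <x^2> consistent with kT/k_lambda: chi-square interval at 99%
    x2_sum <- sum(s / (0.5 * 3))           # sum of x^2
    scaled <- x2_sum / (kt / klam)          # ~ chisq(n)
    n <- length(s)
    expect_gt(scaled, qchisq(0.005, n))
    expect_lt(scaled, qchisq(0.995, n))
  }
})

test_that("generators are byte-reproducible and replica-stable", {
  sched <- lambda_schedule(5)
  a <- sample_harmonic_alchemy(sched, 1, 4, 300, 50, 3, seed = 9)
  b <- sample_harmonic_alchemy(sched, 1, 4, 300, 50, 3, seed = 9)
  expect_identical(a$dhdl$dhdl_kcal_mol, b$dhdl$dhdl_kcal_mol)
  expect_identical(a$u_kn[[2]]$u_kn, b$u_kn[[2]]$u_kn)
  # adding replicas must not reshuffle earlier replicas
  c5 <- sample_harmonic_alchemy(sched, 1, 4, 300, 50, 5, seed = 9)
  expect_identical(
    a$dhdl$dhdl_kcal_mol[a$dhdl$replica <= 3],
    c5$dhdl$dhdl_kcal_mol[c5$dhdl$replica <= 3]
  )
  g1 <- sample_gaussian_dhdl(sched, c(1, 2), 0.4, 0.5, 0.2, 40, 2, seed = 3)
  g2 <- sample_gaussian_dhdl(sched, c(1, 2), 0.4, 0.5, 0.2, 40, 4, seed = 3)
  expect_identical(g1$dhdl_kcal_mol, g2$dhdl_kcal_mol[g2$replica <= 2])
})

test_that("gaussian generator: exact truths, AR(1) correlation, offsets", {
  sched <- lambda_schedule(5)
  # constant noiseless profile: every sample equals the constant
  g <- sample_gaussian_dhdl(sched, profile_coeffs = 2.5, ar1_rho = 0,
                            sigma_within = 0, sigma_replica = 0,
                            n_samples = 20, n_replicas = 2, seed = 1)
  expect_true(all(g$dhdl_kcal_mol == 2.5))
  expect_equal(attr(g, "truth"), 2.5)
  # 12*lambda - 6 integrates to zero; truth from coefficients is exact
  g2 <- sample_gaussian_dhdl(sched, c(-6, 12), 0, 1, 0, 10, 1, seed = 1)
  expect_equal(attr(g2, "truth"), 0)
  # polynomial truth matches numerical quadrature to 1e-10
  coef <- c(0.3, -2, 7, -4.5)
  g3 <- sample_gaussian_dhdl(sched, coef, 0, 1, 0, 10, 1, seed = 1)
  quad <- integrate(function(x) alchemble:::polyval(coef, x), 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(attr(g3, "truth"), quad, tolerance = 1e-10)
  # lag-1 autocorrelation of a long series recovers ar1_rho
  g4 <- sample_gaussian_dhdl(lambda_schedule(2), 0, ar1_rho = 0.6,
                             sigma_within = 1, n_samples = 50000,
                             n_replicas = 1, seed = 5)
  x <- g4$dhdl_kcal_mol[g4$window == 1]
  expect_equal(cor(x[-1], x[-length(x)]), 0.6, tolerance = 0.05)
  # replica-offset SD over many replicas within 20% of sigma_replica
  g5 <- sample_gaussian_dhdl(lambda_schedule(2), 0, 0, sigma_within = 0,
                             sigma_replica = 0.5, n_samples = 2,
                             n_replicas = 150, seed = 8)
  offsets <- tapply(g5$dhdl_kcal_mol, g5$replica, mean)
  expect_equal(sd(offsets), 0.5, tolerance = 0.2)
})

test_that("generator input validation", {
  sched <- lambda_schedule(5)
  expect_error(sample_harmonic_alchemy(sched, -1, 4), "positive")
  expect_error(sample_gaussian_dhdl(sched, numeric(0)), "nonempty")
  expect_error(sample_gaussian_dhdl(sched, 1, ar1_rho = 1), "ar1_rho")
})

test_that("pair dataset encodes the requested bias and noise", {
  p <- build_pair_dataset(30, bias_factor = 1, noise_sd = 0, seed = 2)
  expect_equal(p$ddg_cal, p$ddg_exp)
  expect_true(all(p$ddg_exp_err == 0.41))
  p0 <- build_pair_dataset(10, bias_factor = 0, noise_sd = 0, seed = 2)
  expect_true(all(p0$ddg_cal == 0))
  # reproducible under seed, per-replica columns present
  q <- build_pair_dataset(30, bias_factor = 1, noise_sd = 0, seed = 2)
  expect_identical(p, q)
  expect_equal(alchemble:::replica_cols(p), paste0("rep", 1:5))
  expect_error(build_pair_dataset(5, ddg_exp_range = c(2, 2)), "interval")
})
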