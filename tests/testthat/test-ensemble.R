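test_that("ensemble combination reports mean, replica SD, and SEM", {
  same <- ensemble_combine(c(1, 1, 1))
  expect_equal(same$value, 1)
  expect_equal(same$replica_sd, 0)
  expect_equal(same$error, 0)
  est <- ensemble_combine(c(0, 1, 2))
  expect_equal(est$value, 1)
  expect_equal(est$replica_sd, 1)
  expect_equal(est$error, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(round(est$error, 4), 0.5774)
  expect_error(ensemble_combine(list()), "at least one")
})

test_that("ensemble SEM scales as 1/sqrt(n_replicas)", {
  # fixed replica_sd: the scaling is exact
  mk <- function(vals) ensemble_combine(vals)
  v <- alchemble:::with_seed(5, rnorm(80, sd = 0.5))
  e5 <- mk(v[1:5]); e80 <- mk(v)
  expect_equal(e5$error * sqrt(5) / e5$replica_sd, 1, tolerance = 1e-12)
  expect_equal(e80$error * sqrt(80) / e80$replica_sd, 1, tolerance = 1e-12)
  # on generated ensembles the mean SEM over repeats follows the law
  sched <- lambda_schedule(5)
  sem_of <- function(n_rep) {
    mean(sapply(1:12, function(s) {
      d <- sample_gaussian_dhdl(sched, 1, 0.2, sigma_within = 0.3,
                                sigma_replica = 0.4, n_samples = 40,
                                n_replicas = n_rep, seed = 900 + s)
      ti_estimate(d)$error
    }))
  }
  r <- sem_of(5) / sem_of(20)
  expect_equal(r, 2, tolerance = 0.35)
})

test_that("relative free energies subtract legs with paired replicas", {
  c_leg <- fe_estimate(-10, 0.2, "TI", per_replica = c(-10.1, -9.9, -10))
  s_leg <- fe_estimate(-8, 0.1, "TI", per_replica = c(-8.2, -7.9, -7.9))
  d <- ddg_from_legs(c_leg, s_leg)
  expect_equal(d$value, -2)
  expect_equal(d$error, sqrt(0.2^2 + 0.1^2))
  expect_equal(d$per_replica, c(-1.9, -2.0, -2.1))
  expect_equal(d$value, mean(d$per_replica))
  # self-difference: zero with sqrt(2) error inflation
  self <- ddg_from_legs(c_leg, c_leg)
  expect_equal(self$value, 0)
  expect_equal(self$error, sqrt(2) * 0.2)
  # method mismatch refuses; unequal replica counts warn and unpair
  m_leg <- fe_estimate(-8, 0.1, "MBAR")
  expect_error(ddg_from_legs(c_leg, m_leg), "different estimators")
  s2 <- fe_estimate(-8, 0.1, "TI", per_replica = c(-8, -8))
  expect_warning(d2 <- ddg_from_legs(c_leg, s2), "replica counts differ")
  expect_null(d2$per_replica)
})

test_that("two harmonic legs recover the difference of their truths", {
  sched <- lambda_schedule(13)
  cx <- sample_harmonic_alchemy(sched, 1, 6, 300, 1500, 3, seed = 81)
  sv <- sample_harmonic_alchemy(sched, 1, 2, 300, 1500, 3, seed = 82)
  d <- ddg_from_legs(ti_estimate(cx$dhdl), ti_estimate(sv$dhdl))
  truth <- attr(cx$dhdl, "truth") - attr(sv$dhdl, "truth")
  expect_lt(abs(d$value - truth), 4 * d$error + 0.01)
})

test_that("replica range report summarises spread against sigma_MBAR", {
  r <- replica_range_report(c(1.0, 2.0, 1.5), mbar_errs = c(0.1, 0.1, 0.1))
  expect_equal(r$range, 1)
  expect_equal(r$min, 1)
  expect_equal(r$max, 2)
  expect_equal(r$mean_sigma_mbar, 0.1)
  same <- replica_range_report(rep(2, 4))
  expect_equal(same$sd, 0)
  expect_equal(same$range, 0)
  expect_error(replica_range_report(1.0), "at least 2")
  # replica-dominated ensemble: spread exceeds the asymptotic error
  sim <- small_harmonic(n_samples = 400, n_replicas = 5, seed = 91,
                        sigma_replica = 0.3)
  est <- mbar_estimate(sim$u_kn)
  rep_report <- replica_range_report(est$per_replica, est$per_replica_error)
  expect_gt(rep_report$sd, rep_report$mean_sigma_mbar)
})

test_that("tidy and glance expose estimates as tibbles", {
  est <- ensemble_combine(c(0.5, 0.7, 0.9))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_equal(td$value, c(0.5, 0.7, 0.9))
  gl <- glance(est)
  expect_equal(gl$n_replicas, 3L)
  expect_equal(gl$value, 0.7)
})
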