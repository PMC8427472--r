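test_that("exchange acceptance is a symmetric Metropolis criterion", {
  pot <- toy_potential("harmonic", k_env = 0)
  # identical rungs and positions: Delta = 0, always accepted
  a <- list(lambda = 0, scale = 1, position = -1)
  expect_equal(exchange_acceptance(a, a, pot), 1)
  # identical reduced potentials, different positions: still Delta = 0
  b <- list(lambda = 0, scale = 1, position = 0.4)
  expect_equal(exchange_acceptance(a, b, pot), 1)
  # engineered Delta = log(2): scales 1 vs 0.5, x_i = 0, x_j^2 = 4 log 2
  i <- list(lambda = 0, scale = 1, position = 0)
  j <- list(lambda = 0, scale = 0.5, position = 2 * sqrt(log(2)))
  expect_equal(exchange_acceptance(i, j, pot), 0.5, tolerance = 1e-12)
  expect_equal(exchange_acceptance(j, i, pot),
               exchange_acceptance(i, j, pot))
  # downhill swaps are always accepted
  k <- list(lambda = 0, scale = 0.5, position = 0)
  m <- list(lambda = 0, scale = 1, position = 2)
  expect_equal(exchange_acceptance(m, k, pot), 1)
})

test_that("a single-rung ladder never attempts exchanges", {
  pot <- toy_potential("double_well")
  run <- run_toy_rest(pot, tibble::tibble(lambda = 0, scale = 1),
                      n_steps = 500, seed = 1)
  expect_equal(nrow(run$exchanges), 0)
  expect_equal(nrow(run$trajectories), 50)
})

test_that("identical rungs accept every exchange and attempts are counted", {
  pot <- toy_potential("double_well")
  ladder <- tibble::tibble(lambda = c(0, 0, 0), scale = c(1, 1, 1))
  run <- run_toy_rest(pot, ladder, n_steps = 1000, exchange_interval = 10,
                      seed = 2)
  expect_true(all(run$exchanges$rate == 1))
  # 100 exchange phases alternate between pair sets {1-2} and {2-3}
  phases <- floor(1000 / 10)
  expect_equal(sum(run$exchanges$attempted), phases)
  expect_equal(run$exchanges$attempted, c(50L, 50L))
})

test_that("the scale ladder unlocks barrier crossing for the base replica", {
  # frozen demonstration: 8 kT double well, wells at +/- 2, base replica
  # started in the left well; thresholds fixed from a calibration run
  pot <- toy_potential("double_well", barrier_height = 8,
                       well_separation = 4)
  ladder <- tibble::tibble(lambda = 0,
                           scale = exp(seq(0, log(0.2), length.out = 6)))
  hot <- run_toy_rest(pot, ladder, n_steps = 1e5, exchange_interval = 10,
                      step_size = 0.1, x0 = -2, seed = 1)
  cold <- run_toy_rest(pot, ladder[1, ], n_steps = 1e5, step_size = 0.1,
                       x0 = -2, seed = 1)
  occ_ladder <- mean(hot$trajectories$position[
    hot$trajectories$replica == 1] > 0)
  occ_single <- mean(cold$trajectories$position > 0)
  expect_gt(occ_ladder, 0.1)
  expect_lt(occ_single, 0.01)
  expect_true(all(hot$exchanges$rate >= 0 & hot$exchanges$rate <= 1))
})

test_that("runs are deterministic under the seed", {
  pot <- toy_potential("double_well")
  ladder <- tibble::tibble(lambda = c(0, 0.5), scale = c(1, 0.5))
  a <- run_toy_rest(pot, ladder, 2000, seed = 7)
  b <- run_toy_rest(pot, ladder, 2000, seed = 7)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$exchanges, b$exchanges)
})

test_that("discrete sampler counts every step and reports exchanges", {
  run <- run_discrete_rest(c(0, 2, 0.5), scales = c(1, 0.3),
                           n_steps = 2000, exchange_interval = 5, seed = 3)
  expect_equal(sum(run$counts), 2000)
  expect_equal(unname(run$exchange["attempted"]), 400L)
  expect_lte(run$exchange["accepted"], run$exchange["attempted"])
})
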