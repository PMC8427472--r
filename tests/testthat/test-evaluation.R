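test_that("pair rearrangement flips both values and is an involution", {
  p <- tibble::tibble(
    pair_id = c("a", "b", "c"),
    ddg_exp = c(-1.5, 2.0, 0.0),
    ddg_cal = c(-1.0, -0.5, 0.3),
    rep1 = c(-1.1, -0.4, 0.2),
    rep2 = c(-0.9, -0.6, 0.4)
  )
  r <- rearrange_pairs(p)
  expect_equal(r$ddg_exp, c(1.5, 2.0, 0.0))
  expect_equal(r$ddg_cal, c(1.0, -0.5, 0.3))     # zero-exp pair untouched
  expect_equal(r$rep1, c(1.1, -0.4, 0.2))        # replicas flipped too
  expect_identical(rearrange_pairs(r), r)        # involution
  expect_identical(r$pair_id, p$pair_id)         # order preserved
})

test_that("MUE/MSE/RMSE match the hand-computed fixture", {
  m <- pair_metrics(metric_fixture())
  expect_equal(m$mue, 0.5, tolerance = 1e-12)
  expect_equal(m$mse, -1 / 6, tolerance = 1e-12)
  expect_equal(round(m$mse, 4), -0.1667)
  expect_equal(m$rmse, sqrt(5 / 12), tolerance = 1e-12)
  expect_equal(round(m$rmse, 4), 0.6455)
  # identity: all zeros
  id <- tibble::tibble(ddg_exp = c(1, -2), ddg_cal = c(1, -2))
  expect_equal(unlist(pair_metrics(id)[c("mue", "mse", "rmse")]),
               c(mue = 0, mse = 0, rmse = 0))
  # negating every pair leaves the metrics unchanged
  p <- metric_fixture()
  flipped <- dplyr::mutate(p, ddg_exp = -ddg_exp, ddg_cal = -ddg_cal)
  expect_equal(pair_metrics(flipped), pair_metrics(p))
})

test_that("metric inequalities and permutation invariance hold generally", {
  for (s in 1:25) {
    p <- build_pair_dataset(40, bias_factor = runif(1, 0.3, 1.3),
                            noise_sd = runif(1, 0, 1), seed = s)
    m <- pair_metrics(p)
    expect_gte(m$rmse, m$mue)           # power-mean inequality
    expect_gte(m$mue, abs(m$mse))       # triangle inequality
    perm <- p[sample.int(nrow(p)), ]
    expect_equal(pair_metrics(perm)[-1], m[-1])
  }
})

test_that("regression recovers exact and simulated linear maps", {
  lin <- tibble::tibble(ddg_exp = c(-3, -1, 0.5, 2, 4),
                        ddg_cal = c(-3, -1, 0.5, 2, 4))
  r <- regression_stats(lin)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  shrunk <- dplyr::mutate(lin, ddg_cal = 0.7 * ddg_exp)
  r2 <- regression_stats(shrunk)
  expect_equal(r2$slope, 0.7, tolerance = 1e-12)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)
  expect_equal(r2$pearson_r, 1, tolerance = 1e-12)
  p <- build_pair_dataset(200, bias_factor = 0.7, noise_sd = 0.3, seed = 17)
  expect_gt(regression_stats(p)$slope, 0.6)
  expect_lt(regression_stats(p)$slope, 0.8)
  expect_error(regression_stats(lin[1:2, ]), "at least 3")
  flat <- tibble::tibble(ddg_exp = rep(1, 5), ddg_cal = rnorm(5))
  expect_error(regression_stats(flat), "degenerate")
})

test_that("bootstrap SDs behave like bootstrap theory says", {
  const <- tibble::tibble(ddg_exp = rep(1.2, 10), ddg_cal = rep(0.7, 10))
  expect_equal(bootstrap_metric(const, "mue", n_boot = 50, seed = 1), 0)
  # SD of the MSE approximates sd(deviations)/sqrt(n)
  p <- build_pair_dataset(150, bias_factor = 1, noise_sd = 0.5, seed = 23)
  bs <- bootstrap_metric(p, "mse", n_boot = 1500, seed = 2)
  r <- rearrange_pairs(p)
  theory <- sd(r$ddg_cal - r$ddg_exp) / sqrt(nrow(p))
  expect_equal(bs, theory, tolerance = 0.15)
  # doubling n shrinks the SD by roughly sqrt(2)
  p2 <- build_pair_dataset(300, bias_factor = 1, noise_sd = 0.5, seed = 23)
  bs2 <- bootstrap_metric(p2, "mse", n_boot = 1500, seed = 2)
  expect_equal(bs / bs2, sqrt(2), tolerance = 0.25)
  # determinism under seed
  expect_identical(bootstrap_metric(p, "rmse", 200, seed = 9),
                   bootstrap_metric(p, "rmse", 200, seed = 9))
})

test_that("binned underestimation matches the hand-worked example", {
  b <- binned_underestimation(bin_fixture())
  expect_equal(b$n, c(1L, 2L, 1L, 4L))
  expect_equal(b$pct_underestimated, c(0, 50, 100, 50))
  expect_equal(b$mean_signed_dev, c(0.1, 0, -1, -0.225), tolerance = 1e-12)
  # bin bookkeeping: counts add up, total mean is the weighted bin mean
  expect_equal(sum(b$n[1:3]), b$n[4])
  expect_equal(sum(b$n[1:3] * b$mean_signed_dev[1:3]) / b$n[4],
               b$mean_signed_dev[4])
})

test_that("bins use half-open intervals and report empty bins as NA", {
  p <- tibble::tibble(ddg_exp = c(1.37, 2.73), ddg_cal = c(1.0, 2.0))
  b <- binned_underestimation(p)
  expect_equal(b$n[1:3], c(0L, 1L, 1L))          # edges go to the right bin
  expect_true(is.na(b$pct_underestimated[1]))    # empty bin is NA, not 0
  expect_true(is.na(b$mean_signed_dev[1]))
  perfect <- tibble::tibble(ddg_exp = c(0.5, 2, 3), ddg_cal = c(0.5, 2, 3))
  bp <- binned_underestimation(perfect)
  expect_equal(bp$pct_underestimated[bp$bin == "total"], 0)
  expect_equal(bp$mean_signed_dev[bp$bin == "total"], 0)
  expect_error(binned_underestimation(p, edges = c(2, 1)), "increasing")
})

test_that("underestimation grows with experimental magnitude under shrinkage", {
  hits <- 0
  for (s in 1:50) {
    p <- build_pair_dataset(120, ddg_exp_range = c(-5, 5),
                            bias_factor = 0.7, noise_sd = 0.4, seed = s)
    b <- binned_underestimation(p)
    pct <- b$pct_underestimated[1:3]
    if (!anyNA(pct) && pct[1] <= pct[2] && pct[2] <= pct[3]) hits <- hits + 1
  }
  expect_gte(hits, 26)  # majority vote over seeds
})

test_that("log-unit conversion reproduces the conventional constants", {
  expect_equal(log_units_to_kcal(0), 0)
  expect_equal(round(log_units_to_kcal(0.3, 298.15), 2), 0.41)
  expect_equal(round(log_units_to_kcal(2, 298.15), 2), 2.73)
  # note: the conventional bin edge 1.37 is half the printed 2-log-unit
  # value, not the rounded 1-log-unit conversion (1.36) — which is why
  # binned_underestimation() stores the printed constants verbatim
  expect_equal(round(log_units_to_kcal(1, 298.15), 2), 1.36)
  expect_error(log_units_to_kcal(1, temperature = -5), "positive")
})

test_that("evaluate_pairs assembles a coherent report", {
  p <- build_pair_dataset(60, bias_factor = 0.8, noise_sd = 0.3, seed = 5)
  rep <- evaluate_pairs(p, n_boot = 200, seed = 2)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n_pairs, 60)
  expect_equal(rep$metrics$metric, c("mue", "mse", "rmse"))
  expect_true(all(rep$metrics$boot_sd > 0))
  td <- tidy(rep)
  expect_true(all(c("mue", "slope") %in% td$term))
  gl <- glance(rep)
  expect_equal(gl$n_pairs, 60)
  expect_lt(gl$slope, 1)
  expect_output(print(rep), "ligand pairs")
})
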