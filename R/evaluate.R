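#' Rearrange ligand pairs so that the experimental value is nonnegative
#'
#' A relative free energy is defined up to the direction of the ligand
#' pair: swapping the two ligands negates both the experimental and the
#' calculated value. Benchmark statistics that care about the sign of the
#' deviation (MSE, underestimation counts) are therefore computed after
#' orienting every pair so that \eqn{\Delta\Delta G_{exp} \ge 0}: any
#' record with a negative experimental value has its experimental,
#' calculated, and per-replica values all negated. Pairs with
#' \eqn{\Delta\Delta G_{exp} = 0} are left untouched. The operation is an
#' involution: applying it twice changes nothing.
#'
#' @param pairs Pair tibble with columns `ddg_exp`, `ddg_cal` and optional
#'   `rep1..repN` per-replica columns.
#' @return The tibble with flipped rows, order preserved.
#' @export
#' @examples
#' rearrange_pairs(tibble::tibble(ddg_exp = c(-1.5, 2), ddg_cal = c(-1, -0.5)))
rearrange_pairs <- function(pairs) {
  flip <- pairs$ddg_exp < 0
  cols <- c("ddg_exp", "ddg_cal", replica_cols(pairs))
  pairs[flip, cols] <- -pairs[flip, cols]
  pairs
}

#' Accuracy metrics for calculated vs experimental relative free energies
#'
#' \deqn{\mathrm{MUE} = \frac1n \sum_i |\Delta\Delta G_{exp,i} -
#'   \Delta\Delta G_{cal,i}|,\qquad
#' \mathrm{RMSE} = \sqrt{\frac1n \sum_i (\Delta\Delta G_{exp,i} -
#'   \Delta\Delta G_{cal,i})^2},}
#' \deqn{\mathrm{MSE} = \frac1n \sum_i (\Delta\Delta G_{cal,i} -
#'   \Delta\Delta G_{exp,i})}
#' with the MSE computed after [rearrange_pairs()] (MUE and RMSE are
#' invariant to the rearrangement). A negative MSE indicates systematic
#' underestimation of the experimental differences.
#'
#' @param pairs Pair tibble (need not be pre-rearranged).
#' @return One-row tibble: `n_pairs`, `mue`, `mse`, `rmse` (kcal/mol).
#' @export
#' @examples
#' p <- tibble::tibble(ddg_exp = c(1, -2, 0.5), ddg_cal = c(1.5, -1, 0.5))
#' pair_metrics(p)  # mue 0.5, mse -1/6, rmse 0.6455
pair_metrics <- function(pairs) {
  if (nrow(pairs) < 1) abort("need at least one pair")
  r <- rearrange_pairs(pairs)
  dev <- r$ddg_cal - r$ddg_exp
  tibble::tibble(
    n_pairs = nrow(pairs),
    mue = mean(abs(dev)),
    mse = mean(dev),
    rmse = sqrt(mean(dev^2))
  )
}

#' Regression of calculated on experimental relative free energies
#'
#' Unweighted ordinary least squares
#' \eqn{\Delta\Delta G_{cal} = \alpha\,\Delta\Delta G_{exp} + \beta} on
#' rearranged pairs, plus the Pearson correlation on the same records.
#' A slope below one together with a negative MSE is the signature of
#' multiplicative underestimation.
#'
#' @param pairs Pair tibble with at least 3 records and at least two
#'   distinct experimental values.
#' @return One-row tibble: `slope`, `intercept`, `pearson_r`.
#' @export
regression_stats <- function(pairs) {
  if (nrow(pairs) < 3) abort("need at least 3 pairs")
  r <- rearrange_pairs(pairs)
  if (length(unique(r$ddg_exp)) < 2) abort("degenerate x-variance")
  fit <- lm(ddg_cal ~ ddg_exp, data = r)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r = cor(r$ddg_exp, r$ddg_cal)
  )
}

#' Bootstrap standard deviation of a benchmark metric
#'
#' Resamples ligand pairs with replacement `n_boot` times, recomputes the
#' metric on each resample, and returns the sample SD of the bootstrap
#' distribution. This is the parenthesised uncertainty attached to MUE,
#' MSE and RMSE in benchmark tables: it measures how much the metric would
#' move under a different draw of ligand pairs, not simulation precision.
#'
#' @param pairs Pair tibble (>= 2 records).
#' @param metric One of `"mue"`, `"mse"`, `"rmse"`, `"slope"`,
#'   `"intercept"`, `"pearson_r"`.
#' @param n_boot Number of bootstrap resamples. Default 1000.
#' @param seed Seed controlling the resampling.
#' @return The bootstrap SD (scalar).
#' @export
bootstrap_metric <- function(pairs, metric = c("mue", "mse", "rmse", "slope",
                                               "intercept", "pearson_r"),
                             n_boot = 1000, seed = 1L) {
  metric <- match.arg(metric)
  n <- nrow(pairs)
  if (n < 2) abort("need at least 2 pairs")
  n_boot <- check_count(n_boot, "n_boot")
  fn <- function(p) {
    if (metric %in% c("mue", "mse", "rmse")) pair_metrics(p)[[metric]]
    else regression_stats(p)[[metric]]
  }
  vals <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1, function(i) fn(pairs[i, , drop = FALSE]))
  })
  sd(vals)
}

#' Binned underestimation analysis
#'
#' After orienting every pair so that \eqn{\Delta\Delta G_{exp} \ge 0},
#' splits the pairs into magnitude bins (default edges 1.37 and 2.73
#' kcal/mol, i.e. 1 and 2 log units of activity) and reports, per bin and
#' in total: the pair count, the percentage of pairs with
#' \eqn{\Delta\Delta G_{cal} < \Delta\Delta G_{exp}} (strict inequality;
#' ties count as not underestimated), and the mean signed deviation
#' \eqn{\overline{\Delta\Delta G_{cal} - \Delta\Delta G_{exp}}}. Growing
#' underestimation percentages and increasingly negative mean deviations
#' across bins are the signature of shrinkage bias that worsens for large
#' free-energy differences. Empty bins report `NA`, not zero.
#'
#' Bins are half-open `[lo, hi)`. The printed edges 1.37 and 2.73 are used
#' verbatim by convention; see [log_units_to_kcal()] for the underlying
#' conversion.
#'
#' @param pairs Pair tibble (rearrangement is applied internally).
#' @param edges Increasing positive bin edges (kcal/mol).
#'   Default `c(1.37, 2.73)`.
#' @return Tibble with one row per bin plus a `"total"` row: `bin`, `lo`,
#'   `hi`, `n`, `pct_underestimated`, `mean_signed_dev`.
#' @export
#' @examples
#' p <- tibble::tibble(ddg_exp = c(0.5, 1.5, 2, 3),
#'                     ddg_cal = c(0.6, 1, 2.5, 2))
#' binned_underestimation(p)
binned_underestimation <- function(pairs, edges = c(1.37, 2.73)) {
  if (any(edges <= 0) || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be strictly increasing and positive")
  }
  r <- rearrange_pairs(pairs)
  lo <- c(0, edges)
  hi <- c(edges, Inf)
  bin_of <- findInterval(r$ddg_exp, c(0, edges), rightmost.closed = FALSE)
  per_bin <- purrr::map_dfr(seq_along(lo), function(b) {
    sel <- bin_of == b
    n <- sum(sel)
    tibble::tibble(
      bin = paste0("bin", b),
      lo = lo[b], hi = hi[b],
      n = n,
      pct_underestimated = if (n == 0) NA_real_
                           else 100 * mean(r$ddg_cal[sel] < r$ddg_exp[sel]),
      mean_signed_dev = if (n == 0) NA_real_
                        else mean(r$ddg_cal[sel] - r$ddg_exp[sel])
    )
  })
  total <- tibble::tibble(
    bin = "total", lo = 0, hi = Inf, n = nrow(r),
    pct_underestimated = 100 * mean(r$ddg_cal < r$ddg_exp),
    mean_signed_dev = mean(r$ddg_cal - r$ddg_exp)
  )
  dplyr::bind_rows(per_bin, total)
}

#' Convert log units of binding activity to kcal/mol
#'
#' One log unit of activity (a tenfold change in affinity) corresponds to
#' \eqn{k_B T \ln 10} of free energy: at 298.15 K, 0.3 log units is 0.41
#' kcal/mol (the conventional experimental uncertainty when assays report
#' none) and 2 log units is 2.73 kcal/mol.
#'
#' @param log_units Activity difference in log10 units.
#' @param temperature Kelvin. Default 298.15.
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' log_units_to_kcal(0.3)  # 0.41
#' log_units_to_kcal(2)    # 2.73
log_units_to_kcal <- function(log_units, temperature = 298.15) {
  if (any(temperature <= 0)) abort("`temperature` must be positive")
  log_units * kT(temperature) * log(10)
}

#' Full benchmark evaluation of a ligand-pair table
#'
#' Computes the complete accuracy/precision/bias report for a set of
#' ligand pairs: MUE, MSE and RMSE with bootstrap SDs, OLS regression and
#' Pearson correlation, and the binned underestimation analysis.
#'
#' @param pairs Pair tibble.
#' @param n_boot Bootstrap resamples for the metric SDs. Default 1000.
#' @param seed Seed for the bootstrap.
#' @param edges Bin edges for [binned_underestimation()].
#' @return Object of class `eval_report`: list with `n_pairs`, `metrics`
#'   (tibble `metric`, `value`, `boot_sd`), `regression`, `bins`,
#'   `settings`.
#' @export
#' @examples
#' pairs <- build_pair_dataset(50, bias_factor = 0.8, noise_sd = 0.4,
#'                             seed = 11)
#' evaluate_pairs(pairs, n_boot = 200, seed = 1)
evaluate_pairs <- function(pairs, n_boot = 1000, seed = 1L,
                           edges = c(1.37, 2.73)) {
  m <- pair_metrics(pairs)
  metrics <- tibble::tibble(
    metric = c("mue", "mse", "rmse"),
    value = c(m$mue, m$mse, m$rmse),
    boot_sd = purrr::map_dbl(c("mue", "mse", "rmse"),
                             ~ bootstrap_metric(pairs, .x, n_boot = n_boot,
                                                seed = seed))
  )
  structure(
    list(
      n_pairs = nrow(pairs),
      metrics = metrics,
      regression = regression_stats(pairs),
      bins = binned_underestimation(pairs, edges = edges),
      settings = list(n_boot = n_boot, seed = seed, edges = edges)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d ligand pairs (bootstrap SDs, n_boot = %d)\n",
              x$n_pairs, x$settings$n_boot))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-5s %6.3f (%.3f) kcal/mol\n",
                toupper(m$metric[i]), m$value[i], m$boot_sd[i]))
  }
  cat(sprintf("  slope %.3f, intercept %.3f, Pearson r %.3f\n",
              x$regression$slope, x$regression$intercept,
              x$regression$pearson_r))
  cat("  underestimation by |ddG_exp| bin:\n")
  b <- x$bins
  for (i in seq_len(nrow(b))) {
    cat(sprintf("    %-6s [%4.2f, %4.2f): n=%3d  %5.1f%%  mean dev %6.3f\n",
                b$bin[i], b$lo[i], min(b$hi[i], 99.99), b$n[i],
                b$pct_underestimated[i], b$mean_signed_dev[i]))
  }
  invisible(x)
}

#' @describeIn evaluate_pairs Long tibble of all scalar statistics in the
#'   report.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics |> dplyr::select(term = "metric", estimate = "value",
                               std.error = "boot_sd"),
    tibble::tibble(
      term = c("slope", "intercept", "pearson_r"),
      estimate = c(x$regression$slope, x$regression$intercept,
                   x$regression$pearson_r),
      std.error = NA_real_
    )
  )
}

#' @describeIn evaluate_pairs One-row summary of the headline statistics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    mue = x$metrics$value[x$metrics$metric == "mue"],
    mse = x$metrics$value[x$metrics$metric == "mse"],
    rmse = x$metrics$value[x$metrics$metric == "rmse"],
    slope = x$regression$slope,
    intercept = x$regression$intercept,
    pearson_r = x$regression$pearson_r,
    pct_underestimated = x$bins$pct_underestimated[x$bins$bin == "total"]
  )
}
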