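#' Statistical inefficiency of a correlated time series
#'
#' Returns \eqn{g = 1 + 2\sum_t \hat\tau(t)}, where \eqn{\hat\tau(t)} is the
#' normalized autocorrelation function summed until its first non-positive
#' value (initial-positive-sequence truncation). For white noise
#' \eqn{g \to 1}; for AR(1) with lag-1 correlation \eqn{\rho},
#' \eqn{g \to (1+\rho)/(1-\rho)}. The effective sample size of a series of
#' length n is n/g.
#'
#' @param x Numeric series, length >= 2.
#' @return Statistical inefficiency g >= 1.
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 2) abort("series must have length >= 2")
  v <- var(x) * (n - 1) / n
  if (v == 0) return(1)
  xc <- x - mean(x)
  g <- 1
  for (t in seq_len(n - 1)) {
    ct <- sum(xc[1:(n - t)] * xc[(t + 1):n]) / (n - t) / v
    if (ct <= 0) break
    g <- g + 2 * ct
  }
  max(1, g)
}

#' Mean and autocorrelation-corrected SEM of one window's series
#'
#' The TI integrand at one lambda window is a serially correlated time
#' series; treating its samples as independent understates the error of the
#' window mean. The SEM is corrected by the statistical inefficiency:
#' \eqn{\mathrm{SEM} = s\sqrt{g/n}}, equivalently \eqn{s/\sqrt{n_{eff}}}
#' with \eqn{n_{eff} = n/g}.
#'
#' @param series Numeric series, length >= 2.
#' @param lambda Optional lambda value carried through to the output.
#' @return One-row tibble: `lambda`, `n`, `mean_dhdl`, `sem_dhdl`, `g`,
#'   `n_eff`.
#' @export
#' @examples
#' window_mean_and_sem(rnorm(1000), lambda = 0.5)
window_mean_and_sem <- function(series, lambda = NA_real_) {
  n <- length(series)
  if (n < 2) abort("series must have length >= 2")
  g <- statistical_inefficiency(series)
  s <- sd(series)
  tibble::tibble(
    lambda = lambda,
    n = n,
    mean_dhdl = mean(series),
    sem_dhdl = s * sqrt(g / n),
    g = g,
    n_eff = n / g
  )
}

#' Per-window statistics for every replica of a dU/dlambda ensemble
#'
#' @param dhdl A `dhdl_ensemble` tibble (see [dhdl_ensemble()]).
#' @return Tibble with one row per (replica, window): `replica`, `lambda`,
#'   `n`, `mean_dhdl`, `sem_dhdl`, `g`, `n_eff`.
#' @export
window_stats <- function(dhdl) {
  dhdl |>
    dplyr::group_by(.data$replica, .data$window, .data$lambda) |>
    dplyr::summarise(
      stats = list(window_mean_and_sem(.data$dhdl_kcal_mol,
                                       lambda = .data$lambda[1])),
      .groups = "drop"
    ) |>
    dplyr::select(-"lambda") |>
    tidyr::unnest("stats") |>
    dplyr::arrange(.data$replica, .data$window)
}
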