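#' Sample correlated Gaussian dU/dlambda series around a polynomial profile
#'
#' Emulates the statistical structure of ensemble alchemical MD output
#' without any molecular mechanics: the true window means follow a
#' polynomial profile in lambda, each replica is shifted by a constant
#' offset (replicas start from identical coordinates but different random
#' velocities, so their window averages scatter around the ensemble mean),
#' and samples within a series carry AR(1) serial correlation (MD time
#' series are autocorrelated). The ground-truth free-energy change is the
#' exact polynomial integral \eqn{\int_0^1 \mathrm{profile}(\lambda)\,
#' d\lambda}, computed from the coefficients.
#'
#' @param schedule A [lambda_schedule()].
#' @param profile_coeffs Polynomial coefficients of the true
#'   \eqn{\langle dU/d\lambda \rangle} curve, lowest order first
#'   (kcal/mol).
#' @param ar1_rho Lag-1 autocorrelation of the within-series AR(1) noise,
#'   in \[0, 1).
#' @param sigma_within Marginal SD of the within-series noise (kcal/mol).
#' @param sigma_replica SD of the per-replica constant offsets (kcal/mol).
#' @param n_samples Samples per window per replica.
#' @param n_replicas Number of replicas. Default 5.
#' @param seed Root seed.
#' @param temperature Kelvin (metadata only; the generator is athermal).
#' @return A `dhdl_ensemble` tibble with `truth` attribute equal to the
#'   exact polynomial integral.
#' @export
#' @examples
#' sched <- lambda_schedule(13)
#' d <- sample_gaussian_dhdl(sched, profile_coeffs = c(-6, 12),
#'                           ar1_rho = 0.5, sigma_within = 1,
#'                           sigma_replica = 0.2, n_samples = 50, seed = 7)
#' attr(d, "truth")  # integral of 12*lambda - 6 over [0,1] = 0
sample_gaussian_dhdl <- function(schedule, profile_coeffs, ar1_rho = 0,
                                 sigma_within = 1, sigma_replica = 0,
                                 n_samples = 1000, n_replicas = 5, seed = 1L,
                                 temperature = 298.15) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  if (length(profile_coeffs) == 0) abort("`profile_coeffs` must be nonempty")
  if (!is.numeric(ar1_rho) || abs(ar1_rho) >= 1) abort("need |ar1_rho| < 1")
  stopifnot(sigma_within >= 0, sigma_replica >= 0)
  n_samples <- check_count(n_samples, "n_samples")
  n_replicas <- check_count(n_replicas, "n_replicas")

  lam <- schedule$lambda
  K <- length(lam)
  profile <- polyval(profile_coeffs, lam)
  truth <- poly_integral_01(profile_coeffs)

  rows <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    rs <- replica_seed(seed, r)
    offset <- if (sigma_replica > 0) {
      with_seed(window_seed(rs, 0L), rnorm(1, 0, sigma_replica))
    } else 0
    series <- matrix(NA_real_, nrow = n_samples, ncol = K)
    for (w in seq_len(K)) {
      noise <- with_seed(window_seed(rs, w),
                         ar1_series(n_samples, ar1_rho, sigma_within))
      series[, w] <- profile[w] + offset + noise
    }
    rows[[r]] <- tibble::tibble(
      replica = r,
      window = rep(seq_len(K), each = n_samples),
      lambda = rep(lam, each = n_samples),
      step = rep(seq_len(n_samples), times = K),
      dhdl_kcal_mol = as.vector(series)
    )
  }
  dhdl_ensemble(dplyr::bind_rows(rows), schedule = schedule,
                temperature = temperature, truth = truth)
}

# stationary AR(1) with marginal SD `sigma` and lag-1 correlation `rho`
ar1_series <- function(n, rho, sigma) {
  if (sigma == 0) return(numeric(n))
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n)
  e <- rnorm(n)
  x[1] <- sigma * e[1]
  if (n > 1 && rho != 0) {
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov_sd * e[t]
  } else if (n > 1) {
    x[2:n] <- sigma * e[2:n]
  }
  x
}

# evaluate polynomial with coefficients lowest-order first
polyval <- function(coeffs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coeffs)) out <- out + coeffs[i] * x^(i - 1)
  out
}

# exact integral of the polynomial over [0, 1]
poly_integral_01 <- function(coeffs) {
  sum(coeffs / seq_along(coeffs))
}
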