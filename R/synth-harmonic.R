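#' Sample an exactly solvable harmonic alchemical transformation
#'
#' Generates per-window dU/dlambda time series and a reduced-potential
#' cross-evaluation matrix for the analytic test system
#' \deqn{U_\lambda(x) = \tfrac12 k_\lambda x^2,} where the spring constant
#' interpolates between the end states `k0` and `k1`. With linear mixing
#' (`k_interpolation = "linear"`, the default)
#' \eqn{k_\lambda = (1-\lambda)k_0 + \lambda k_1} and
#' \eqn{\partial U/\partial\lambda = \tfrac12 (k_1 - k_0) x^2}; with
#' geometric mixing \eqn{k_\lambda = k_0^{1-\lambda} k_1^{\lambda}} and
#' \eqn{\partial U/\partial\lambda = \tfrac12 \ln(k_1/k_0)\, k_\lambda x^2}.
#' Either way the exact free-energy change is
#' \deqn{\Delta G = \tfrac{k_B T}{2}\,\ln(k_1/k_0),}
#' which is attached to both outputs as ground truth. Geometric mixing
#' keeps adjacent-window phase-space overlap roughly constant and is the
#' better choice when `k1/k0` is large.
#'
#' Each window is sampled i.i.d. from the exact Boltzmann distribution
#' \eqn{x \sim N(0, k_B T / k_\lambda)}; the reduced potentials
#' \eqn{u_{kn} = U_k(x_n)/k_B T} are cross-evaluated for every sample under
#' every window.
#'
#' `sigma_replica > 0` jitters each replica's log end-state constant
#' (\eqn{\ln k_1}) by a mean-zero Gaussian scaled so that the induced
#' per-replica free-energy offsets have standard deviation `sigma_replica`
#' (kcal/mol). This emulates replicas that, through incomplete sampling,
#' effectively explore slightly different Hamiltonians — the mechanism by
#' which replica-to-replica scatter can dwarf the per-replica asymptotic
#' (MBAR) error.
#'
#' @param schedule A [lambda_schedule()].
#' @param k0,k1 End-state spring constants (> 0), energy/length^2 with
#'   energy in kcal/mol.
#' @param temperature Kelvin. Default 298.15.
#' @param n_samples Samples per window per replica.
#' @param n_replicas Number of replicas. Default 5.
#' @param seed Root seed; all draws derive from it deterministically.
#' @param sigma_replica SD (kcal/mol) of per-replica free-energy offsets
#'   implemented as log-k1 jitter. Default 0 (all replicas share the exact
#'   Hamiltonian).
#' @param k_interpolation `"linear"` (default) or `"geometric"` mixing of
#'   the spring constant along lambda.
#' @return A list with elements
#'   \describe{
#'     \item{dhdl}{a `dhdl_ensemble` tibble (`replica`, `window`, `lambda`,
#'       `step`, `dhdl_kcal_mol`) with attributes `temperature`, `truth`
#'       (kcal/mol) and `schedule`;}
#'     \item{u_kn}{a list of one `reduced_potential_set` per replica (see
#'       [reduced_potential_set()]), each carrying the same `truth`.}
#'   }
#' @export
#' @examples
#' sched <- lambda_schedule(5)
#' sim <- sample_harmonic_alchemy(sched, k0 = 1, k1 = 4, temperature = 300,
#'                                n_samples = 100, n_replicas = 2, seed = 1)
#' attr(sim$dhdl, "truth")  # (kT/2) log 4
sample_harmonic_alchemy <- function(schedule, k0, k1, temperature = 298.15,
                                    n_samples = 1000, n_replicas = 5,
                                    seed = 1L, sigma_replica = 0,
                                    k_interpolation = c("linear", "geometric")) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  if (!is.numeric(k0) || !is.numeric(k1) || k0 <= 0 || k1 <= 0) {
    abort("`k0` and `k1` must be positive")
  }
  stopifnot(temperature > 0, sigma_replica >= 0)
  k_interpolation <- match.arg(k_interpolation)
  n_samples <- check_count(n_samples, "n_samples")
  n_replicas <- check_count(n_replicas, "n_replicas")

  kt <- kT(temperature)
  truth <- (kt / 2) * log(k1 / k0)
  lam <- schedule$lambda
  K <- length(lam)

  k_of_lambda <- function(k1r) {
    if (k_interpolation == "linear") (1 - lam) * k0 + lam * k1r
    else k0^(1 - lam) * k1r^lam
  }
  dkdl_of_lambda <- function(k_lam, k1r) {
    if (k_interpolation == "linear") rep(k1r - k0, length(k_lam))
    else log(k1r / k0) * k_lam
  }

  dhdl_rows <- vector("list", n_replicas)
  rps <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    rs <- replica_seed(seed, r)
    # replica-level Hamiltonian jitter (log-k1), drawn from its own stream
    k1r <- k1
    if (sigma_replica > 0) {
      eps <- with_seed(window_seed(rs, 0L), rnorm(1, 0, 2 * sigma_replica / kt))
      k1r <- k1 * exp(eps)
    }
    k_lam <- k_of_lambda(k1r)
    dkdl <- dkdl_of_lambda(k_lam, k1r)
    x <- matrix(NA_real_, nrow = n_samples, ncol = K)
    for (w in seq_len(K)) {
      x[, w] <- with_seed(window_seed(rs, w),
                          rnorm(n_samples, 0, sqrt(kt / k_lam[w])))
    }
    dhdl_rows[[r]] <- tibble::tibble(
      replica = r,
      window = rep(seq_len(K), each = n_samples),
      lambda = rep(lam, each = n_samples),
      step = rep(seq_len(n_samples), times = K),
      dhdl_kcal_mol = 0.5 * rep(dkdl, each = n_samples) * as.vector(x)^2
    )
    # u_kn: K states x (K * n_samples) cross-evaluation, dimensionless
    xs <- as.vector(x)  # samples ordered by generating window
    u_kn <- 0.5 * outer(k_lam, xs^2) / kt
    rps[[r]] <- reduced_potential_set(u_kn, counts = rep(n_samples, K),
                                      temperature = temperature,
                                      truth = truth, lambda = lam)
  }

  dhdl <- dhdl_ensemble(dplyr::bind_rows(dhdl_rows), schedule = schedule,
                        temperature = temperature, truth = truth)
  list(dhdl = dhdl, u_kn = setNames(rps, paste0("rep", seq_len(n_replicas))))
}

#' Construct a dU/dlambda ensemble table
#'
#' Validates and classes a long-format tibble of per-replica, per-window
#' dU/dlambda samples. Every (replica, window) combination implied by the
#' data must be fully populated.
#'
#' @param data Tibble with columns `replica`, `window`, `lambda`, `step`,
#'   `dhdl_kcal_mol`.
#' @param schedule Optional [lambda_schedule()]; when given, the table's
#'   lambda values are cross-checked against it.
#' @param temperature Kelvin.
#' @param truth Optional known free-energy change (kcal/mol).
#' @return The tibble with class `dhdl_ensemble` and metadata attributes.
#' @export
dhdl_ensemble <- function(data, schedule = NULL, temperature = 298.15,
                          truth = NULL) {
  req <- c("replica", "window", "lambda", "step", "dhdl_kcal_mol")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(data$dhdl_kcal_mol))) abort("non-finite dhdl values")
  lam_by_window <- dplyr::distinct(data, .data$window, .data$lambda)
  if (anyDuplicated(lam_by_window$window)) {
    abort("inconsistent lambda values within a window")
  }
  grid <- tidyr::expand_grid(replica = unique(data$replica),
                             window = unique(data$window))
  have <- dplyr::distinct(data, .data$replica, .data$window)
  gap <- dplyr::anti_join(grid, have, by = c("replica", "window"))
  if (nrow(gap)) {
    abort(sprintf("missing series for replica %s, window %s",
                  gap$replica[1], gap$window[1]))
  }
  if (!is.null(schedule)) {
    lam_by_window <- dplyr::arrange(lam_by_window, .data$window)
    if (!isTRUE(all.equal(lam_by_window$lambda, schedule$lambda))) {
      abort("table lambda grid does not match the schedule")
    }
  }
  structure(tibble::as_tibble(data),
            class = c("dhdl_ensemble", class(tibble::tibble())),
            schedule = schedule, temperature = temperature, truth = truth)
}

#' Construct a reduced-potential matrix for MBAR
#'
#' @param u_kn Numeric matrix, K states by N total samples, of dimensionless
#'   reduced energies \eqn{u_k(x_n) = U_k(x_n)/k_B T}.
#' @param counts Integer vector of per-state sample counts, summing to N.
#'   Samples must be ordered by generating state.
#' @param temperature Kelvin (used to convert MBAR free energies to
#'   kcal/mol).
#' @param truth Optional known free-energy change (kcal/mol).
#' @param lambda Optional per-state lambda values.
#' @return An object of class `reduced_potential_set`.
#' @export
reduced_potential_set <- function(u_kn, counts, temperature = 298.15,
                                  truth = NULL, lambda = NULL) {
  u_kn <- as.matrix(u_kn)
  counts <- as.integer(counts)
  if (length(counts) != nrow(u_kn)) {
    abort("length(counts) must equal nrow(u_kn)")
  }
  if (any(counts < 0) || sum(counts) != ncol(u_kn)) {
    abort("counts must be nonnegative and sum to ncol(u_kn)")
  }
  if (any(!is.finite(u_kn))) abort("u_kn must be finite")
  structure(list(u_kn = u_kn, counts = counts, temperature = temperature,
                 truth = truth, lambda = lambda),
            class = "reduced_potential_set")
}

#' @export
print.reduced_potential_set <- function(x, ...) {
  cat(sprintf("<reduced_potential_set> %d states, %d samples, T = %g K\n",
              nrow(x$u_kn), ncol(x$u_kn), x$temperature))
  if (!is.null(x$truth)) cat(sprintf("  truth: %.4f kcal/mol\n", x$truth))
  invisible(x)
}
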