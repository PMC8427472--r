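#' Solve the MBAR equations for a set of sampled states
#'
#' From-scratch multistate Bennett acceptance ratio solver. Given reduced
#' potentials \eqn{u_{kn} = U_k(x_n)/k_BT} for every sample under every
#' state, the dimensionless free energies solve the self-consistent
#' equations
#' \deqn{f_k = -\ln \sum_n \frac{e^{-u_{kn}}}
#'   {\sum_l N_l\, e^{f_l - u_{ln}}},}
#' anchored at \eqn{f_1 = 0}. The solver warm-starts with self-consistent
#' iteration and finishes with a damped Newton method on the equivalent
#' convex objective; all reductions use log-sum-exp for overflow safety.
#' Convergence is declared when the largest free-energy update falls below
#' `tol`; non-convergence is reported with a warning, never silently.
#'
#' Asymptotic uncertainties come from the standard MBAR covariance
#' estimate \eqn{\hat\Theta} computed via the singular value decomposition
#' of the weight matrix (a pseudo-inverse handles the anchor degeneracy);
#' the per-state error reported is that of \eqn{f_k - f_1}.
#'
#' @param rp A [reduced_potential_set()]. Every state must carry at least
#'   one sample.
#' @param tol Convergence tolerance on \eqn{\max_k |\Delta f_k|}.
#'   Default 1e-10.
#' @param max_iter Maximum total iterations. Default 10000.
#' @return An object of class `mbar_fit`: list with `states` (tibble:
#'   `state`, `lambda`, `n_samples`, `f`, `dG_kcal_mol`, `dG_err_kcal_mol`),
#'   `theta` (covariance of the \eqn{f_k}), `converged`, `n_iter`,
#'   `max_residual`, `temperature`, `truth`.
#' @export
#' @examples
#' sched <- lambda_schedule(5)
#' sim <- sample_harmonic_alchemy(sched, 1, 4, 300, n_samples = 500,
#'                                n_replicas = 1, seed = 3)
#' fit <- mbar_solve(sim$u_kn[[1]])
#' fit$states
mbar_solve <- function(rp, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(rp, "reduced_potential_set"))
  u_kn <- rp$u_kn
  counts <- rp$counts
  K <- nrow(u_kn)
  if (K < 2) abort("need at least 2 states")
  if (any(counts == 0)) {
    abort("every sampled state must have at least one sample")
  }
  logN <- log(counts)
  kt <- kT(rp$temperature)

  # log mixture denominator per sample: logsumexp_l(log N_l + f_l - u_ln)
  log_denom <- function(f) col_logsumexp(logN + f - u_kn)
  sc_update <- function(f) {
    ld <- log_denom(f)
    fn <- -apply(-sweep(u_kn, 2, ld, "+"), 1, logsumexp)
    fn - fn[1]
  }

  f <- numeric(K)
  iter <- 0L
  converged <- FALSE
  # self-consistent warm start
  for (i in seq_len(min(50L, max_iter))) {
    fn <- sc_update(f)
    iter <- iter + 1L
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) { converged <- TRUE; break }
  }

  # convex objective for line search: sum_n ln sum_k N_k e^{f_k - u_kn}
  # - sum_k N_k f_k (minimized at the MBAR solution)
  objective <- function(f) sum(log_denom(f)) - sum(counts * f)

  if (!converged) {
    while (iter < max_iter) {
      ld <- log_denom(f)
      W <- exp(sweep(f - u_kn, 2, ld, "-"))      # K x N, sum_k N_k W_kn = 1
      rs <- rowSums(W)
      grad <- counts * (rs - 1)
      H <- diag(counts * rs, K) - (W * counts) %*% t(W * counts)
      step <- numeric(K)
      sol <- try(solve(H[-1, -1, drop = FALSE], -grad[-1]), silent = TRUE)
      if (inherits(sol, "try-error") || any(!is.finite(sol))) {
        fn <- sc_update(f)
        iter <- iter + 1L
        delta <- max(abs(fn - f))
        f <- fn
        if (delta < tol) { converged <- TRUE; break }
        next
      }
      step[-1] <- sol
      obj0 <- objective(f)
      alpha <- 1
      repeat {
        fn <- f + alpha * step
        fn <- fn - fn[1]
        if (is.finite(objective(fn)) && objective(fn) <= obj0 + 1e-13) break
        alpha <- alpha / 2
        if (alpha < 1e-8) { fn <- sc_update(f); break }
      }
      iter <- iter + 1L
      delta <- max(abs(fn - f))
      f <- fn
      if (delta < tol) { converged <- TRUE; break }
    }
  }

  residual <- max(abs(sc_update(f) - f))
  if (!converged) {
    warn(sprintf("MBAR did not converge in %d iterations (last residual %.3g)",
                 iter, residual))
  }

  theta <- mbar_covariance(u_kn, counts, f)
  var_rel_anchor <- pmax(0, diag(theta) + theta[1, 1] - 2 * theta[1, ])

  states <- tibble::tibble(
    state = seq_len(K),
    lambda = if (is.null(rp$lambda)) NA_real_ else rp$lambda,
    n_samples = counts,
    f = f,
    dG_kcal_mol = kt * f,
    dG_err_kcal_mol = kt * sqrt(var_rel_anchor)
  )
  structure(list(states = states, theta = theta, converged = converged,
                 n_iter = iter, max_residual = residual,
                 temperature = rp$temperature, truth = rp$truth),
            class = "mbar_fit")
}

# Asymptotic covariance of the dimensionless free energies: with the
# N x K weight matrix W (W_nk = e^{f_k - u_kn} / sum_l N_l e^{f_l - u_ln})
# and its SVD W = U S V', Theta = V S (I - S V' diag(N) V S)^+ S V'.
mbar_covariance <- function(u_kn, counts, f) {
  ld <- col_logsumexp(log(counts) + f - u_kn)
  W <- t(exp(sweep(f - u_kn, 2, ld, "-")))   # N x K
  sv <- svd(W, nu = 0)
  S <- sv$d
  V <- sv$v
  # S V' diag(N) V S without forming the N x N diagonal
  M <- diag(S, length(S)) %*% t(V) %*% (V * counts) %*% diag(S, length(S))
  inner <- pinv_sym(diag(length(S)) - M)
  theta <- V %*% diag(S, length(S)) %*% inner %*% diag(S, length(S)) %*% t(V)
  (theta + t(theta)) / 2
}

# Moore-Penrose pseudo-inverse of a symmetric matrix
pinv_sym <- function(m, rtol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > rtol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Free-energy difference between two MBAR states
#'
#' @param fit An `mbar_fit` from [mbar_solve()].
#' @param from,to State indices; defaults span the full transformation
#'   (first to last state).
#' @return A [fe_estimate()] with `method = "MBAR"`; value and asymptotic
#'   error in kcal/mol.
#' @export
mbar_delta_g <- function(fit, from = 1L, to = nrow(fit$states)) {
  stopifnot(inherits(fit, "mbar_fit"))
  kt <- kT(fit$temperature)
  v <- fit$theta[from, from] + fit$theta[to, to] - 2 * fit$theta[from, to]
  fe_estimate(
    value = kt * (fit$states$f[to] - fit$states$f[from]),
    error = kt * sqrt(max(0, v)),
    method = "MBAR"
  )
}

#' Ensemble MBAR estimate over per-replica reduced-potential sets
#'
#' Solves MBAR independently for each replica, takes the end-to-end
#' free-energy difference of each, and combines the replicas with
#' [ensemble_combine()]. Per-replica asymptotic errors are retained in
#' `per_replica_error` so that ensemble spread and asymptotic error can be
#' compared (they routinely disagree; the replica SD is the honest
#' precision measure).
#'
#' @param rps List of [reduced_potential_set()] objects, one per replica.
#' @param ... Passed to [mbar_solve()].
#' @return A [fe_estimate()] with `method = "MBAR"`.
#' @export
mbar_estimate <- function(rps, ...) {
  per <- purrr::map(rps, function(rp) mbar_delta_g(mbar_solve(rp, ...)))
  est <- ensemble_combine(per)
  est$method <- "MBAR"
  est
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("<mbar_fit> %d states, %s, %d iterations\n",
              nrow(x$states),
              if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(x$states, ...)
  invisible(x)
}
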