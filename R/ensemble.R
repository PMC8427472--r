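#' Free-energy estimate container
#'
#' Holds a free-energy change (or relative change) with its uncertainty,
#' the estimator that produced it, and — for ensemble estimates — the
#' per-replica values behind it.
#'
#' @param value Estimate in kcal/mol.
#' @param error Reported uncertainty in kcal/mol (>= 0). Its meaning
#'   depends on provenance: stochastic-integral error for a single-replica
#'   TI estimate, asymptotic error for MBAR, standard error of the replica
#'   mean for ensemble estimates.
#' @param method `"TI"` or `"MBAR"`.
#' @param per_replica Optional per-replica values (kcal/mol).
#' @param replica_sd Optional sample SD of the per-replica values.
#' @param per_replica_error Optional per-replica method errors.
#' @return Object of class `fe_estimate`.
#' @export
fe_estimate <- function(value, error, method = c("TI", "MBAR"),
                        per_replica = NULL, replica_sd = NULL,
                        per_replica_error = NULL) {
  method <- match.arg(method)
  if (!is.finite(value)) abort("`value` must be finite")
  if (is.na(error) || error < 0) {
    if (!is.na(error)) abort("`error` must be >= 0")
  }
  structure(
    list(value = value, error = error, method = method,
         per_replica = per_replica, replica_sd = replica_sd,
         per_replica_error = per_replica_error),
    class = "fe_estimate"
  )
}

#' Combine replica estimates into an ensemble estimate
#'
#' The ensemble value is the arithmetic mean of the replica values; the
#' precision is quantified by the sample standard deviation across
#' replicas (n - 1 denominator), and the reported error is the standard
#' error of the mean, `replica_sd / sqrt(n)`. Each replica's own method
#' error (stochastic-integral or asymptotic) is kept separately and never
#' merged into the ensemble error.
#'
#' @param estimates A list of [fe_estimate()] objects (one per replica) or
#'   a numeric vector of per-replica values.
#' @return A [fe_estimate()] carrying `per_replica`, `replica_sd` and, when
#'   available, `per_replica_error`.
#' @export
#' @examples
#' ensemble_combine(c(0, 1, 2))  # value 1, replica_sd 1, error 1/sqrt(3)
ensemble_combine <- function(estimates) {
  if (is.numeric(estimates)) {
    vals <- estimates
    errs <- NULL
    method <- "TI"
  } else {
    if (length(estimates) == 0) abort("need at least one replica")
    stopifnot(all(purrr::map_lgl(estimates, inherits, "fe_estimate")))
    vals <- purrr::map_dbl(estimates, "value")
    errs <- purrr::map_dbl(estimates, "error")
    method <- estimates[[1]]$method
  }
  n <- length(vals)
  if (n == 0) abort("need at least one replica")
  rsd <- if (n > 1) sd(vals) else NA_real_
  fe_estimate(
    value = mean(vals),
    error = if (n > 1) rsd / sqrt(n) else NA_real_,
    method = method,
    per_replica = vals,
    replica_sd = rsd,
    per_replica_error = errs
  )
}

#' Relative free energy from the two alchemical legs
#'
#' \eqn{\Delta\Delta G = \Delta G_{complex} - \Delta G_{solvent}}, with
#' errors propagated in quadrature. When both legs carry per-replica
#' values with equal replica counts, replicas are paired by index (the
#' protocol runs the same ensemble size on both legs) and the per-replica
#' differences and their SD are retained; with unequal counts the function
#' falls back to unpaired propagation with a warning.
#'
#' @param complex_leg,solvent_leg [fe_estimate()] objects with matching
#'   `method`.
#' @return A [fe_estimate()] for the relative free-energy change.
#' @export
ddg_from_legs <- function(complex_leg, solvent_leg) {
  stopifnot(inherits(complex_leg, "fe_estimate"),
            inherits(solvent_leg, "fe_estimate"))
  if (!identical(complex_leg$method, solvent_leg$method)) {
    abort("legs were computed with different estimators")
  }
  per <- NULL
  rsd <- NULL
  pc <- complex_leg$per_replica
  ps <- solvent_leg$per_replica
  if (!is.null(pc) && !is.null(ps)) {
    if (length(pc) == length(ps)) {
      per <- pc - ps
      rsd <- if (length(per) > 1) sd(per) else NA_real_
    } else {
      warn("replica counts differ between legs; using unpaired propagation")
    }
  }
  fe_estimate(
    value = complex_leg$value - solvent_leg$value,
    error = sqrt(complex_leg$error^2 + solvent_leg$error^2),
    method = complex_leg$method,
    per_replica = per,
    replica_sd = rsd
  )
}

#' Replica-range summary of an ensemble of relative free energies
#'
#' Summarises the spread of per-replica relative free-energy values the
#' way ensemble benchmark tables report it — average with SD, min to max
#' with range — alongside the mean per-replica asymptotic (MBAR) error.
#' When replica-level variability dominates, the range and SD exceed the
#' asymptotic error by a wide margin, which is exactly why one-off
#' calculations with small reported errors are not trustworthy.
#'
#' @param per_replica_ddg Numeric vector of per-replica values (>= 2).
#' @param mbar_errs Optional numeric vector of per-replica asymptotic
#'   errors.
#' @return One-row tibble: `n_replicas`, `mean`, `sd`, `min`, `max`,
#'   `range`, `mean_sigma_mbar`.
#' @export
#' @examples
#' replica_range_report(c(1.0, 2.0, 1.5), mbar_errs = c(0.05, 0.06, 0.05))
replica_range_report <- function(per_replica_ddg, mbar_errs = NULL) {
  if (length(per_replica_ddg) < 2) abort("need at least 2 replicas")
  tibble::tibble(
    n_replicas = length(per_replica_ddg),
    mean = mean(per_replica_ddg),
    sd = sd(per_replica_ddg),
    min = min(per_replica_ddg),
    max = max(per_replica_ddg),
    range = max(per_replica_ddg) - min(per_replica_ddg),
    mean_sigma_mbar = if (is.null(mbar_errs)) NA_real_ else mean(mbar_errs)
  )
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("<fe_estimate> %s: %.4f +/- %.4f kcal/mol\n",
              x$method, x$value, x$error))
  if (!is.null(x$per_replica)) {
    cat(sprintf("  %d replicas, SD %.4f: %s\n", length(x$per_replica),
                x$replica_sd, paste(sprintf("%.3f", x$per_replica),
                                    collapse = " ")))
  }
  invisible(x)
}

#' @describeIn fe_estimate One row per replica (or one row total when no
#'   replicas are attached): `replica`, `value`, `error`.
#' @param x A `fe_estimate`.
#' @param ... Unused.
#' @export
tidy.fe_estimate <- function(x, ...) {
  if (is.null(x$per_replica)) {
    return(tibble::tibble(replica = NA_integer_, value = x$value,
                          error = x$error, method = x$method))
  }
  tibble::tibble(
    replica = seq_along(x$per_replica),
    value = x$per_replica,
    error = if (is.null(x$per_replica_error)) NA_real_ else x$per_replica_error,
    method = x$method
  )
}

#' @describeIn fe_estimate One-row summary: `method`, `value`, `error`,
#'   `replica_sd`, `n_replicas`.
#' @export
glance.fe_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    value = x$value,
    error = x$error,
    replica_sd = x$replica_sd %||% NA_real_,
    n_replicas = if (is.null(x$per_replica)) NA_integer_
                 else length(x$per_replica)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
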