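#' Build a lambda-window schedule with electrostatic scaling factors
#'
#' Constructs the alchemical coupling-parameter grid used by both the
#' synthetic generators and the estimators, together with the two linear
#' electrostatic scaling functions of a dual-topology transformation: the
#' charges of the disappearing group are decoupled linearly between
#' \eqn{\lambda = 0} and `elec_off_end` and are fully off beyond it, while
#' the charges of the appearing group are coupled linearly from
#' `elec_on_start` to \eqn{\lambda = 1} and are fully off before it.
#' Removing charges before atoms vanish (and introducing them only after
#' atoms appear) avoids unshielded point charges at the endpoints.
#'
#' Only the window count of the protocol is fixed by convention (13); the
#' default grid is evenly spaced on \[0, 1\] and can be overridden via
#' `lambdas`.
#'
#' @param n_windows Number of lambda windows (>= 2). Default 13.
#' @param elec_off_end Lambda at which disappearing-group electrostatics
#'   reach zero. Default 0.55.
#' @param elec_on_start Lambda at which appearing-group electrostatics start
#'   to grow. Default 0.45.
#' @param lambdas Optional explicit lambda grid (strictly increasing, first
#'   0, last 1); overrides `n_windows`.
#' @return A tibble of class `lambda_schedule` with columns `window`,
#'   `lambda`, `elec_off_scale`, `elec_on_scale`.
#' @export
#' @examples
#' sched <- lambda_schedule(13)
#' sched[sched$lambda >= 0.5, ]
lambda_schedule <- function(n_windows = 13, elec_off_end = 0.55,
                            elec_on_start = 0.45, lambdas = NULL) {
  if (is.null(lambdas)) {
    n_windows <- check_count(n_windows, "n_windows", min = 2L)
    lambdas <- seq(0, 1, length.out = n_windows)
  } else {
    if (length(lambdas) < 2 || any(diff(lambdas) <= 0) ||
        lambdas[1] != 0 || lambdas[length(lambdas)] != 1) {
      abort("`lambdas` must be strictly increasing from 0 to 1")
    }
  }
  if (!(elec_off_end > 0 && elec_off_end < 1) ||
      !(elec_on_start > 0 && elec_on_start < 1) ||
      elec_on_start > elec_off_end) {
    abort("need 0 < elec_on_start <= elec_off_end < 1")
  }
  out <- tibble::tibble(
    window = seq_along(lambdas),
    lambda = as.numeric(lambdas),
    elec_off_scale = elec_off_scale(lambdas, elec_off_end),
    elec_on_scale = elec_on_scale(lambdas, elec_on_start)
  )
  structure(out,
            class = c("lambda_schedule", class(out)),
            elec_off_end = elec_off_end,
            elec_on_start = elec_on_start)
}

#' Electrostatic scaling of the disappearing group
#'
#' Linear decoupling: 1 at \eqn{\lambda = 0}, reaching 0 at `elec_off_end`
#' and completely off beyond it.
#'
#' @param lambda Numeric vector of lambda values in \[0, 1\].
#' @param elec_off_end Endpoint of the linear ramp (default 0.55).
#' @return Scaling factors in \[0, 1\].
#' @export
elec_off_scale <- function(lambda, elec_off_end = 0.55) {
  pmax(0, 1 - lambda / elec_off_end)
}

#' Electrostatic scaling of the appearing group
#'
#' Linear coupling: 0 up to `elec_on_start`, rising linearly to 1 at
#' \eqn{\lambda = 1}.
#'
#' @param lambda Numeric vector of lambda values in \[0, 1\].
#' @param elec_on_start Start of the linear ramp (default 0.45).
#' @return Scaling factors in \[0, 1\].
#' @export
elec_on_scale <- function(lambda, elec_on_start = 0.45) {
  pmax(0, (lambda - elec_on_start) / (1 - elec_on_start))
}

# trapezoid quadrature weights for an ordered lambda grid; sum to the
# interval length (1 for a full schedule)
trapezoid_weights <- function(lambda) {
  k <- length(lambda)
  stopifnot(k >= 2)
  d <- diff(lambda)
  w <- numeric(k)
  w[1] <- d[1] / 2
  w[k] <- d[k - 1] / 2
  if (k > 2) w[2:(k - 1)] <- (d[-(k - 1)] + d[-1]) / 2
  w
}

# natural-cubic-spline quadrature weights: integrate the cardinal basis
# splines, so the spline integral is sum(w * y) for any data y
spline_weights <- function(lambda) {
  k <- length(lambda)
  vapply(seq_len(k), function(i) {
    y <- numeric(k); y[i] <- 1
    sf <- stats::splinefun(lambda, y, method = "natural")
    integrate(sf, lambda[1], lambda[k], subdivisions = 500L,
              rel.tol = 1e-10)$value
  }, numeric(1))
}
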