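#' Analytic one-dimensional REST test potential
#'
#' Defines a reduced (dimensionless) potential split into a "solute" term
#' — the part whose interactions are softened along the
#' effective-temperature ladder — and an unscaled "environment" term, the
#' REST2 convention. A replica at ladder rung \eqn{(\lambda, s)} feels
#' \deqn{u_{\lambda,s}(x) = s\,[u_{solute}(x) + \lambda\,u_{bias}(x)] +
#'   u_{env}(x),}
#' where the `double_well` solute term is
#' \eqn{B\,[(x/a)^2 - 1]^2} with barrier height `B` (in kT) and wells at
#' \eqn{\pm a}, the optional linear bias \eqn{c\,x} plays the role of the
#' alchemical coupling, and the environment is a weak harmonic restraint
#' \eqn{\tfrac12 k_{env} x^2}. Scaling only the solute term by
#' \eqn{s \in (0, 1]} lowers the barrier for the "hot" replicas without
#' touching the environment, exactly the mechanism solute tempering uses
#' to enhance barrier crossing.
#'
#' @param form `"double_well"` or `"harmonic"` (solute term
#'   \eqn{\tfrac12 x^2}, no barrier; useful for exact checks).
#' @param barrier_height Barrier of the double well in kT. Default 8.
#' @param well_separation Distance between the two minima (wells at
#'   +/- half of it). Default 2.
#' @param bias_coeff Coefficient of the lambda-coupled linear bias term.
#'   Default 0.
#' @param k_env Spring constant of the environment restraint. Default 0.05.
#' @return Object of class `toy_potential`: list of functions `solute(x)`,
#'   `bias(x)`, `env(x)` and `reduced(x, lambda, scale)`.
#' @export
#' @examples
#' pot <- toy_potential("double_well", barrier_height = 8)
#' pot$reduced(0, lambda = 0, scale = 1)    # barrier top
#' pot$reduced(1, lambda = 0, scale = 1)    # well bottom (plus restraint)
toy_potential <- function(form = c("double_well", "harmonic"),
                          barrier_height = 8, well_separation = 2,
                          bias_coeff = 0, k_env = 0.05) {
  form <- match.arg(form)
  stopifnot(barrier_height >= 0, well_separation > 0, k_env >= 0)
  a <- well_separation / 2
  solute <- if (form == "double_well") {
    function(x) barrier_height * ((x / a)^2 - 1)^2
  } else {
    function(x) 0.5 * x^2
  }
  bias <- function(x) bias_coeff * x
  env <- function(x) 0.5 * k_env * x^2
  structure(
    list(
      form = form, barrier_height = barrier_height,
      well_separation = well_separation, bias_coeff = bias_coeff,
      k_env = k_env, solute = solute, bias = bias, env = env,
      reduced = function(x, lambda, scale) {
        scale * (solute(x) + lambda * bias(x)) + env(x)
      }
    ),
    class = "toy_potential"
  )
}

#' Metropolis acceptance probability for a replica-exchange swap
#'
#' Configurations of two replicas are swapped with probability
#' \eqn{\min(1, e^{-\Delta})}, where
#' \deqn{\Delta = [u_i(x_j) + u_j(x_i)] - [u_i(x_i) + u_j(x_j)]}
#' in the replicas' reduced potentials. The criterion is symmetric in the
#' two replicas and accepts every downhill (\eqn{\Delta \le 0}) swap.
#'
#' @param state_i,state_j Lists with elements `lambda`, `scale`,
#'   `position`.
#' @param potential A [toy_potential()].
#' @return Acceptance probability in \[0, 1\].
#' @export
#' @examples
#' pot <- toy_potential("double_well")
#' a <- list(lambda = 0, scale = 1, position = -1)
#' b <- list(lambda = 0, scale = 0.5, position = 0.8)
#' exchange_acceptance(a, b, pot)
exchange_acceptance <- function(state_i, state_j, potential) {
  u <- potential$reduced
  d <- (u(state_j$position, state_i$lambda, state_i$scale) +
        u(state_i$position, state_j$lambda, state_j$scale)) -
       (u(state_i$position, state_i$lambda, state_i$scale) +
        u(state_j$position, state_j$lambda, state_j$scale))
  if (!is.finite(d)) abort("non-finite reduced energies in exchange")
  min(1, exp(-d))
}

#' Run a toy lambda-REST replica-exchange simulation
#'
#' Each ladder rung holds one replica sampled by Gaussian random-walk
#' Metropolis in its own reduced potential; every `exchange_interval`
#' steps, swaps are attempted between neighbouring rungs, alternating
#' odd/even neighbour pairs between successive exchange phases. With a
#' single rung no exchanges are ever attempted, which makes the ladder-on
#' / ladder-off comparison a controlled demonstration of what the exchange
#' machinery buys: the base (unscaled) replica inherits barrier crossings
#' made by the hot end of the ladder.
#'
#' @param potential A [toy_potential()].
#' @param ladder Tibble or data frame with columns `lambda` and `scale`
#'   (one row per rung, base replica first).
#' @param n_steps Total Metropolis steps per replica (>= 1).
#' @param exchange_interval Steps between exchange phases. Default 10.
#' @param step_size SD of the Gaussian move proposal. Default 0.4.
#' @param x0 Initial position for every replica. Default -1 (left well).
#' @param seed Seed; the run is fully deterministic given it.
#' @param thin Record every `thin`-th step. Default 10.
#' @return Object of class `rest_run`: list with `trajectories` (tibble
#'   `step`, `replica`, `lambda`, `scale`, `position`), `exchanges`
#'   (tibble `pair`, `attempted`, `accepted`, `rate`) and `move_acceptance`
#'   (per-replica move acceptance rates).
#' @export
run_toy_rest <- function(potential, ladder, n_steps, exchange_interval = 10,
                         step_size = 0.4, x0 = -1, seed = 1L, thin = 10) {
  stopifnot(inherits(potential, "toy_potential"))
  ladder <- tibble::as_tibble(ladder)
  stopifnot(all(c("lambda", "scale") %in% names(ladder)), nrow(ladder) >= 1)
  n_steps <- check_count(n_steps, "n_steps")
  exchange_interval <- check_count(exchange_interval, "exchange_interval")
  R <- nrow(ladder)
  u <- potential$reduced
  lam <- ladder$lambda
  sca <- ladder$scale

  n_rec <- floor(n_steps / thin)
  traj <- matrix(NA_real_, nrow = n_rec, ncol = R)
  att <- acc <- integer(max(R - 1, 1))
  moves_acc <- integer(R)

  with_seed(seed, {
    x <- rep(x0, R)
    ux <- u(x, lam, sca)
    phase <- 0L
    for (step in seq_len(n_steps)) {
      # vectorised Metropolis move for all replicas
      prop <- x + rnorm(R, 0, step_size)
      uprop <- u(prop, lam, sca)
      ok <- log(runif(R)) < (ux - uprop)
      x[ok] <- prop[ok]
      ux[ok] <- uprop[ok]
      moves_acc <- moves_acc + ok
      # exchange phase: alternate odd/even neighbour pairs
      if (R > 1 && step %% exchange_interval == 0) {
        first <- if (phase %% 2L == 0L) 1L else 2L
        phase <- phase + 1L
        ii <- if (first > R - 1L) integer(0) else seq(first, R - 1L, by = 2L)
        for (i in ii) {
          j <- i + 1L
          att[i] <- att[i] + 1L
          d <- (u(x[j], lam[i], sca[i]) + u(x[i], lam[j], sca[j])) -
               (ux[i] + ux[j])
          if (log(runif(1)) < -d) {
            tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
            ux[i] <- u(x[i], lam[i], sca[i])
            ux[j] <- u(x[j], lam[j], sca[j])
            acc[i] <- acc[i] + 1L
          }
        }
      }
      if (step %% thin == 0) traj[step %/% thin, ] <- x
    }
  })

  trajectories <- tibble::tibble(
    step = rep(seq_len(n_rec) * thin, times = R),
    replica = rep(seq_len(R), each = n_rec),
    lambda = rep(lam, each = n_rec),
    scale = rep(sca, each = n_rec),
    position = as.vector(traj)
  )
  exchanges <- if (R > 1) {
    tibble::tibble(
      pair = paste0(seq_len(R - 1), "-", seq_len(R - 1) + 1),
      attempted = att,
      accepted = acc,
      rate = ifelse(att > 0, acc / att, NA_real_)
    )
  } else {
    tibble::tibble(pair = character(), attempted = integer(),
                   accepted = integer(), rate = numeric())
  }
  structure(
    list(trajectories = trajectories, exchanges = exchanges,
         move_acceptance = moves_acc / n_steps, ladder = ladder,
         n_steps = n_steps, exchange_interval = exchange_interval,
         seed = seed),
    class = "rest_run"
  )
}

#' Discrete-state REST sampler on a three-site double well
#'
#' A minimal, exactly enumerable counterpart of [run_toy_rest()]: each
#' replica lives on sites \eqn{\{1, 2, 3\}} with site energies `energies`
#' scaled by its ladder factor, moves by Metropolis proposals to a uniform
#' random neighbouring site (off-grid proposals are rejected in place),
#' and neighbouring replicas attempt configuration swaps every
#' `exchange_interval` steps. Both the move and the exchange kernel leave
#' the product of the replicas' Gibbs distributions invariant, so the
#' empirical joint distribution converges to that product — which can be
#' checked against exact enumeration (the stationary eigenvector of the
#' composite transition matrix).
#'
#' @param energies Numeric length-3 site energies in kT (e.g.
#'   `c(0, b, 0)` for a barrier of height b).
#' @param scales Per-replica scaling factors of the site energies.
#' @param n_steps Number of Metropolis steps per replica.
#' @param exchange_interval Steps between exchange attempts. Default 5.
#' @param seed Seed.
#' @return List with `counts` (R-dimensional contingency table of joint
#'   site occupancy, one margin per replica), `n_steps`, `exchange`
#'   (attempted/accepted).
#' @export
run_discrete_rest <- function(energies, scales, n_steps,
                              exchange_interval = 5, seed = 1L) {
  stopifnot(length(energies) == 3, all(scales > 0))
  n_steps <- check_count(n_steps, "n_steps")
  R <- length(scales)
  S <- 3L
  counts <- array(0L, dim = rep(S, R))
  att <- 0L; acc <- 0L

  with_seed(seed, {
    x <- rep(1L, R)
    # pre-drawn randomness in blocks to keep the loop cheap
    block <- 100000L
    for (start in seq(1L, n_steps, by = block)) {
      nb <- min(block, n_steps - start + 1L)
      prop_dir <- matrix(sample(c(-1L, 1L), nb * R, replace = TRUE), nb, R)
      u_move <- matrix(runif(nb * R), nb, R)
      u_swap <- runif(nb)
      for (t in seq_len(nb)) {
        gstep <- start + t - 1L
        for (r in seq_len(R)) {
          p <- x[r] + prop_dir[t, r]
          if (p >= 1L && p <= S) {
            d <- scales[r] * (energies[p] - energies[x[r]])
            if (u_move[t, r] < exp(-d)) x[r] <- p
          }
        }
        if (R > 1 && gstep %% exchange_interval == 0L) {
          i <- 1L + (gstep %/% exchange_interval) %% (R - 1L)
          j <- i + 1L
          att <- att + 1L
          d <- (scales[i] - scales[j]) * (energies[x[j]] - energies[x[i]])
          if (u_swap[t] < exp(-d)) {
            tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
            acc <- acc + 1L
          }
        }
        idx <- matrix(x, 1L)
        counts[idx] <- counts[idx] + 1L
      }
    }
  })
  list(counts = counts, n_steps = n_steps,
       exchange = c(attempted = att, accepted = acc))
}
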