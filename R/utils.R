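# Internal helpers: seeded RNG streams and numerically safe reductions.

# Large prime < 2^31 used to fold derived seeds back into set.seed()'s range.
SEED_MOD <- 2147483629

# Derive the seed for one replica from the root seed. Stable in the sense
# that adding replicas never reshuffles the streams of earlier replicas.
replica_seed <- function(seed, replica) {
  (as.double(seed) + 6151 * as.double(replica)) %% SEED_MOD
}

# Per-(replica, window) stream: changing the number of windows or samples
# in one window leaves every other window's draws untouched.
window_seed <- function(rseed, window) {
  (as.double(rseed) + 7919 * as.double(window)) %% SEED_MOD
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% SEED_MOD))
  expr
}

# log(sum(exp(x))) without overflow; x a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix (returns one value per column).
col_logsumexp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(substitute(x))))
  }
  as.integer(x)
}
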