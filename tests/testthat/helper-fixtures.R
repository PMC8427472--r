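# Shared fixtures, all built in code.

# three-pair table whose rearranged metrics are known by hand:
# pair 2 flips to (2.0, 1.0); deviations (cal - exp) = 0.5, -1.0, 0.0
metric_fixture <- function() {
  tibble::tibble(
    pair_id = c("a", "b", "c"),
    ddg_exp = c(1.0, -2.0, 0.5),
    ddg_cal = c(1.5, -1.0, 0.5)
  )
}

# four rearranged pairs spanning the three magnitude bins
bin_fixture <- function() {
  tibble::tibble(
    pair_id = letters[1:4],
    ddg_exp = c(0.5, 1.5, 2.0, 3.0),
    ddg_cal = c(0.6, 1.0, 2.5, 2.0)
  )
}

# small harmonic simulation reused across estimator tests
small_harmonic <- function(n_samples = 2000, n_replicas = 3, seed = 101,
                           k0 = 1, k1 = 4, temperature = 300, ...) {
  sample_harmonic_alchemy(lambda_schedule(13), k0 = k0, k1 = k1,
                          temperature = temperature, n_samples = n_samples,
                          n_replicas = n_replicas, seed = seed, ...)
}

harmonic_truth <- function(k0 = 1, k1 = 4, temperature = 300) {
  0.5 * 1.9872e-3 * temperature * log(k1 / k0)
}

# combined uncertainty of an ensemble estimate: between-replica SEM and
# mean within-replica method error (itself averaged over replicas),
# added in quadrature
combined_sigma <- function(est) {
  n <- length(est$per_replica)
  sqrt(est$error^2 + (mean(est$per_replica_error) / sqrt(n))^2)
}
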