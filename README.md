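# alchemble

Ensemble-based analysis of alchemical relative binding free-energy
calculations, in R.

Relative binding free energies (ΔΔG) between pairs of congeneric ligands
are routinely computed by alchemical molecular dynamics: a coupling
parameter λ morphs one ligand into the other over a set of simulation
windows, and the free-energy change of each leg (ligand in protein, ligand
in solvent) is estimated by thermodynamic integration,

    ΔG = ∫₀¹ ⟨∂U/∂λ⟩ dλ ,

or by the multistate Bennett acceptance ratio (MBAR), whose dimensionless
free energies solve

    f_k = −ln Σₙ exp(−u_kn) / Σₗ Nₗ exp(f_l − u_ln) .

Because MD trajectories are chaotic, a single simulation is not
reproducible: honest error bars require an *ensemble* of replicas started
from identical coordinates with randomised velocities, with the replica
standard deviation — not the per-run asymptotic error — quantifying
precision. Benchmark accuracy against experiment is summarised by MUE,
MSE and RMSE (with ligand pairs sign-rearranged so ΔΔG_exp ≥ 0),
regression slope/intercept, bootstrap SDs, and a binned analysis of how
often calculations *underestimate* large experimental differences — the
signature of shrinkage bias reported for replica-exchange solute-tempering
(REST) protocols.

`alchemble` provides that entire analysis chain at desk scale, for people
who want to study or teach its statistical machinery without proprietary
MD engines:

* **Synthetic generators with exact ground truth** — a harmonic-oscillator
  alchemy whose ΔG = (kT/2)·ln(k1/k0) is known analytically (emitting both
  dU/dλ series and u_kn matrices), a Gaussian dU/dλ generator with AR(1)
  serial correlation and replica offsets, and a ligand-pair benchmark
  generator with controllable multiplicative bias.
* **Estimators** — TI with autocorrelation-corrected stochastic-integral
  error propagation, a from-scratch MBAR solver (self-consistent +
  damped-Newton, log-sum-exp, SVD-based asymptotic covariance), ensemble
  combination, and leg subtraction.
* **A toy λ-REST sampler** — Metropolis replicas on analytic 1-D
  potentials with a solute-tempering scale ladder and neighbour exchanges,
  including an exactly enumerable discrete variant for detailed-balance
  checks.
* **Evaluation statistics** — `rearrange_pairs()`, `pair_metrics()`,
  `regression_stats()`, `bootstrap_metric()`, `binned_underestimation()`,
  `log_units_to_kcal()`, all tibble-in/tibble-out with `tidy()`/`glance()`
  methods and ggplot2 helpers.

## Worked example

```r
library(alchemble)

# 13-window schedule with the standard electrostatic decouple/couple ramps
sched <- lambda_schedule(13)

# exactly solvable alchemy: 5 replicas x 5000 samples per window
sim <- sample_harmonic_alchemy(sched, k0 = 1, k1 = 4, temperature = 300,
                               n_samples = 5000, n_replicas = 5, seed = 42)
attr(sim$dhdl, "truth")
#> [1] 0.4132266

ti_estimate(sim$dhdl)
#> <fe_estimate> TI: 0.4152 +/- 0.0007 kcal/mol
#>   5 replicas, SD 0.0015: 0.415 0.414 0.415 0.415 0.418

mbar_estimate(sim$u_kn)
#> <fe_estimate> MBAR: 0.4135 +/- 0.0007 kcal/mol
#>   5 replicas, SD 0.0016: 0.413 0.412 0.413 0.413 0.416
```

Both estimators recover the analytic 0.4132 kcal/mol within their
uncertainties; the TI value carries a small upward composite-trapezoid
discretisation bias on this convex integrand (compare
`ti_estimate(sim$dhdl, quadrature = "spline")`).

Benchmark statistics on a deliberately biased synthetic dataset:

```r
pairs <- build_pair_dataset(200, bias_factor = 0.7, noise_sd = 0.3, seed = 1)
evaluate_pairs(pairs, n_boot = 1000, seed = 1)
#> <eval_report> 200 ligand pairs (bootstrap SDs, n_boot = 1000)
#>   MUE    0.598 (0.027) kcal/mol
#>   MSE   -0.579 (0.029) kcal/mol
#>   RMSE   0.712 (0.028) kcal/mol
#>   slope 0.737, intercept -0.094, Pearson r 0.941
#>   underestimation by |ddG_exp| bin:
#>     bin1   [0.00, 1.37): n= 81   84.0%  mean dev -0.293
#>     bin2   [1.37, 2.73): n= 68   98.5%  mean dev -0.645
#>     bin3   [2.73, 99.99): n= 51  100.0%  mean dev -0.946
#>     total  [0.00, 99.99): n=200   93.0%  mean dev -0.579
```

The report recovers the injected shrinkage: slope ≈ 0.7, negative MSE,
and an underestimation percentage that grows with the experimental
magnitude (bins split at the conventional 1.37 and 2.73 kcal/mol, i.e.
1 and 2 log units of binding activity).

The same analysis runs end to end from the shell:

```sh
Rscript inst/scripts/alchemble pipeline --seed 1 --pairs 20 \
    --estimator ti --bias 0.8 --noise 0.2 --out results/demo
```

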