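---
title: "Methods: ensemble alchemical free-energy analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble alchemical free-energy analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemble)
```

## What this package models

Alchemical relative free-energy calculations morph one ligand into
another along a coupling parameter $\lambda \in [0, 1]$, run once with the
ligand bound to the protein and once free in solvent, and report
$\Delta\Delta G = \Delta G_{complex} - \Delta G_{solvent}$ for comparison
with experimental affinity differences. Two statistical layers sit on top
of the raw simulations, and those layers — not the molecular mechanics —
are what `alchemble` implements:

1. **Estimation.** Thermodynamic integration (TI) integrates the window
   averages $\langle \partial U/\partial\lambda\rangle$ over a schedule of
   windows; MBAR solves self-consistent equations over reduced-potential
   cross-evaluations of all samples under all states.
2. **Uncertainty quantification.** MD trajectories are chaotic, so
   independent replicas started with randomised velocities scatter far
   more than any single run's internal error estimate suggests. The
   protocol emulated here runs an ensemble of five replicas per leg and
   reports the replica mean, with precision measured by the replica
   standard deviation.

Everything runs on synthetic inputs with analytically known answers, so
every estimator can be validated against exact ground truth.

## The synthetic generators and what they do (and do not) emulate

**Harmonic alchemy** (`sample_harmonic_alchemy()`). The potential is
$U_\lambda(x) = \tfrac12 k_\lambda x^2$ with $k_\lambda$ interpolating
between `k0` and `k1`; each window is sampled i.i.d. from its exact
Boltzmann distribution, and $\Delta G = (k_BT/2)\ln(k_1/k_0)$ exactly.
This is the oracle system: it exercises the full TI and MBAR code paths
(dU/dλ series, u_kn cross-evaluation, error propagation) with zero model
error. Two interpolations are provided:

* *linear*, $k_\lambda = (1-\lambda)k_0 + \lambda k_1$ — the default, the
  simplest mixing rule;
* *geometric*, $k_\lambda = k_0^{1-\lambda}k_1^{\lambda}$ — used by the
  pipeline's MBAR path, because with large $k_1/k_0$ linear mixing
  concentrates essentially the whole change in the first window and
  leaves MBAR with no phase-space overlap to work with. Both give the
  same analytic $\Delta G$.

**Gaussian dU/dλ** (`sample_gaussian_dhdl()`). Window series are drawn
around a polynomial profile in $\lambda$ whose exact integral is the
ground truth, with two noise structures taken from real ensemble output:
AR(1) serial correlation within a series (MD time series are
autocorrelated; the statistical-inefficiency machinery needs something to
correct) and a constant per-replica offset (replicas exploring different
conformational basins shift their whole profile). The offset is the
*simplest* structure reproducing replica-to-replica scatter; it is a
modelling choice, not a claim about MD. The harmonic generator's
`sigma_replica` argument implements the analogous mechanism as mean-zero
jitter of $\ln k_1$, i.e. each replica samples a slightly perturbed
Hamiltonian — which is how incomplete sampling actually manifests — so
that replica spread can dominate the MBAR asymptotic error, as observed
in ensemble benchmarks of production codes.

**Pair benchmark** (`build_pair_dataset()`). Experimental values are
uniform on a signed range; calculated values are
$b\cdot\Delta\Delta G_{exp} + \varepsilon$. The multiplicative factor
$b < 1$ emulates the systematic shrinkage (underestimation of large
differences) attributed to REST-based protocols; per-replica columns are
jittered about the calculated value. Experimental uncertainty defaults to
0.41 kcal/mol — 0.3 log units of activity — the conventional figure when
assays report none.

What the generators do **not** emulate: force fields, solvent, soft-core
van der Waals potentials (the harmonic system has no endpoint
singularity, so none is needed), dual-topology atom mapping, or any
engine file format. Passing tests therefore demonstrate the correctness
of the *statistical analysis*, not the fidelity of any MD engine.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| windows | 13 evenly spaced on [0,1] | protocol convention fixes the count only; spacing is user-overridable (`lambdas`) since no canonical grid exists |
| replicas | 5 | the established ensemble protocol size |
| electrostatic decouple end | λ = 0.55 | disappearing charges ramp linearly to zero here, off beyond |
| electrostatic couple start | λ = 0.45 | appearing charges grow linearly from here to 1 |
| temperature | 298.15 K | with $k_B = 1.9872\times10^{-3}$ kcal/mol/K |
| experimental error | 0.41 kcal/mol | 0.3 log units at 298.15 K |
| bin edges | 1.37, 2.73 kcal/mol | the conventional printed constants (1 and 2 log units). Note 1.37 is half of 2.73 rather than the rounded 1-log-unit conversion (1.36); the edges are stored verbatim so outputs match the convention, while `log_units_to_kcal()` performs the exact conversion |
| bootstrap resamples | 1000 | pair-level resampling; the resampling unit and count are choices, labelled as such in outputs |

Simulation "duration" is parameterised as samples per window; mapping
samples to nanoseconds depends on the engine's autocorrelation time and
is out of scope.

## Estimator details and numerical choices

**Window statistics.** The SEM of a window mean uses the statistical
inefficiency $g = 1 + 2\sum_t \hat\tau(t)$ with the autocorrelation sum
truncated at its first non-positive term (initial-positive-sequence
heuristic): standard, cheap, and testable against the AR(1) closed form
$g = (1+\rho)/(1-\rho)$.

**TI.** Composite trapezoid quadrature; the integral error treats window
means as independent, $\sigma^2_{TI} = \sum_i w_i^2\,\mathrm{sem}_i^2$
(the stochastic-integral view). Trapezoid carries an $O(h^2)$
discretisation bias on curved integrands — visible on the harmonic
oracle, where it is comparable to the ensemble SEM at protocol scale — so
a natural-cubic-spline quadrature is available via
`ti_integrate(..., quadrature = "spline")` for sensitivity checks. The
spline integral is still linear in the window means (cardinal-basis
weights), so the same error propagation applies.

**MBAR.** Self-consistent iteration (50 sweeps) warm-starts a damped
Newton solver on the equivalent convex objective; log-sum-exp throughout;
tolerance $10^{-10}$ on $\max_k|\Delta f_k|$, at most $10^4$ iterations,
with non-convergence reported by warning. The asymptotic covariance is
the standard estimator computed from the SVD of the weight matrix with a
pseudo-inverse absorbing the anchor degeneracy ($f_1 = 0$); errors are
reported per difference relative to the anchor. Tests pin the exact
invariances (row shifts move anchored differences by exactly the shift;
per-sample constants cancel) and calibrate the reported error against
replicate scatter.

**Ensembles.** `ensemble_combine()` reports the replica mean, the
replica SD ($n-1$ denominator) and the SEM; each replica's own method
error is retained separately and never silently merged — whether
production error bars should combine within-replica and between-replica
components is genuinely unsettled, so both are exposed.
`ddg_from_legs()` pairs replicas by index when both legs carry equal
counts (the protocol runs equal ensembles per leg) and falls back to
unpaired quadrature propagation with a warning otherwise.

**Degenerate inputs.** Constant series yield zero SEM and $g = 1$;
schedules must be strictly increasing from 0 to 1; every sampled MBAR
state must carry samples; pairs with $\Delta\Delta G_{exp} = 0$ are not
flipped by the rearrangement (involution preserved) and land in the first
bin; underestimation uses strict inequality, so ties count as not
underestimated; empty bins report `NA`, never a fake 0%.

## The toy REST sampler

Replica exchange with solute tempering scales the interactions of a
chosen "hot region" with its environment, so hot replicas cross barriers
the physical replica cannot, and neighbour exchanges hand those
configurations down the ladder. `run_toy_rest()` reproduces exactly this
machinery on analytic 1-D potentials: the reduced potential of a rung
with scale $s$ is $s\,[u_{solute} + \lambda u_{bias}] + u_{env}$ (the
REST2 convention — only the solute term is tempered), moves are Gaussian
random-walk Metropolis, and neighbour swaps use the symmetric criterion
$\min(1, e^{-\Delta})$ with
$\Delta = [u_i(x_j) + u_j(x_i)] - [u_i(x_i) + u_j(x_j)]$, alternating
odd/even neighbour pairs.

The shipped demonstration freezes an 8 kT double well with wells at
±2, a 6-rung geometric scale ladder from 1 to 0.2 (illustrative — no
canonical ladder exists), step size 0.1 and $10^5$ steps: the base
replica of the ladder visits the far well more than 10% of the time while
a single replica stays below 1% (thresholds fixed once from a calibration
run at a fixed seed; barrier crossing is a rare event, so the single-replica
occupancy varies over seeds).

`run_discrete_rest()` is the exactly enumerable counterpart: three sites,
two replicas, the same move/exchange kernels. Every kernel preserves the
product of the replicas' Gibbs distributions, so the empirical joint
occupancy must converge to the stationary eigenvector of the composite
transition matrix — which the acceptance suite verifies to within 1%
total-variation distance at $10^6$ steps.

The sampler demonstrates the exchange *machinery* only. It neither
supports nor refutes any claim about why REST protocols bias production
free-energy predictions; the shrinkage emulation in the pair generator is
an assumption, not a mechanism.

## Design choices where the design was open

* **λ spacing**: only the window count is conventional; evenly spaced by
  default, overridable. Flagged rather than guessed.
* **Quadrature**: trapezoid named as the default because it makes the
  weight algebra transparent and testable; spline behind a flag.
* **Replica pairing**: by index, because the emulated protocol runs equal
  replica counts per leg.
* **Rearrangement boundary**: $\Delta\Delta G_{exp} = 0$ pairs are left
  untouched — flipping them would be arbitrary and break the involution.
* **RNG streams**: one root seed; per-replica and per-window seeds are
  derived arithmetically (fixed multipliers mod a prime below $2^{31}$)
  so that enlarging the ensemble or refining one window never reshuffles
  draws elsewhere, and regeneration is byte-identical.
* **Reports**: JSON artifacts carry a schema version and no timestamps,
  so identical configurations produce byte-identical files.

## Problem sizes

The validation suite uses desk-scale sizes chosen to keep every check
sharp but cheap: the harmonic oracle runs at the emulated protocol scale
(13 windows × 5 replicas × 5000 samples per window); shrinkage-bias
recovery uses 200 pairs over 50 seeds; SEM-scaling checks average 30
datasets at each of 5/20/80 replicas; the discrete detailed-balance check
runs $10^6$ steps. The complete test suite and the acceptance script each
finish in a few minutes on one CPU.

## Known limitations

* The generators produce Gaussian/AR(1)/offset structure only; real
  dU/dλ distributions can be heavy-tailed and multimodal, and replica
  scatter in production data need not be an additive offset.
* The MBAR asymptotic covariance assumes i.i.d. samples within states;
  correlated samples should be subsampled upstream (the statistical
  inefficiency is available for exactly that), which the package does not
  do automatically.
* TI's trapezoid bias is visible whenever the integrand curves between
  windows; the spline option mitigates but does not eliminate it.
* The toy REST sampler is one-dimensional and reduced-unit; it says
  nothing quantitative about molecular systems.
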