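---
title: "Stochastic tissue growth: birth-death and refractory-period models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic tissue growth: birth-death and refractory-period models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuegrowth)
```

## The models and their assumptions

`tissuegrowth` treats tissue size as a pure population count `n(t)`. Both
models are branching processes: cells act independently, there is no
spatial structure, no motility, no crowding, and no bound on population
size. These assumptions buy exact solvability; they also mean the models
are only credible over times during which cell density does not change
enough for mechanics to matter.

**Markovian birth-death model.** Each cell divides with rate `sigma` and
dies with rate `kappa`, independent of its history. The sign of
`sigma - kappa` fixes the dynamical phase (`classify_phase()`): decline,
growth, or the critical homeostatic state `sigma == kappa` where the mean
is constant but fluctuations are anomalous - the variance grows linearly
forever, the connected correlation `Cc(t1, t2)` depends only on the
earlier time, the Pearson correlation decays as `sqrt(t1/t2)` and the
correlation time is infinite. Homeostasis in this picture is not a quiet
steady state but a critical point: individual tissues wander widely (and
ultimately go extinct with probability 1) even though the average is flat.

**Refractory-period model.** The Markovian model lets a newborn cell
divide again immediately, which real cell cycles forbid. The second model
makes division age-dependent: rate `gamma0` once the cell's age (time
since last division) exceeds a refractory period `T`, zero before.
Apoptosis is dropped (`gamma0` can be read as an effective net rate), so
this model lives in the growth phase. Division is synchronizing - starting
from cells of age zero, proliferation proceeds in waves at roughly
multiples of `T` that damp out as cycles desynchronize. All of this is
captured by the pole spectrum `refractory_poles()`: the real dominant pole
`s_0` is the long-run (Malthusian) growth rate, and the first complex pole
sets the oscillation period `2*pi/Im(s_1) ~ T` when `gamma0 * T >> 1`.

```{r}
p <- refractory_params(gamma0 = 1, T = 1)
effective_rate(p)
oscillation_period(refractory_params(10, 1))
```

## Parameters that matter

| Parameter | Meaning | Units | Typical value here |
|---|---|---|---|
| `sigma`, `kappa` | proliferation / apoptosis rates | 1/time | 0.015-0.03 |
| `gamma0` | post-refractory division rate | 1/time | 0.5-20 |
| `T` | refractory period (cell-cycle floor) | time | 0-2 |
| `n0` | initial cells (all age 0) | cells | 50 |
| `dt` | simulation step | time | 1 (Markov), 0.01 (refractory) |
| `K` | pole-expansion branch cutoff | - | 50 |

The reference parameter values (`sigma`/`kappa` in {0.015, 0.03},
`n0 = 50`, 200-500 samples) are the ones the figure-level experiments use;
`reproduce_experiment()` regenerates those ensembles.

## Numerical choices

- **Variance at the critical point.** The closed-form variance is a 0/0
  expression at `sigma == kappa`. `var_markov()` evaluates it as
  `n0 (sigma+kappa) t e^u expm1(u)/u` with `u = (sigma-kappa) t`, which is
  exact in the limit and free of catastrophic cancellation; exact equality
  `sigma == kappa` selects the critical branch `2 n0 kappa t`.
- **Pearson correlation in log space.** For large horizons the variances
  overflow double precision, so `pearson_correlation_markov()` combines
  log-variances; `t2 = Inf` returns the closed-form plateau. Note the
  plateau implied by the model's covariance and variance formulas is
  `sqrt(1 - e^{-(sigma-kappa) t1})`; a widely quoted form without the
  square root is inconsistent with those same formulas, and an independent
  event-driven Monte-Carlo check agrees with the square-root form, which
  is what this package implements and tests.
- **Pole expansion of the non-Markovian mean.** Branches are truncated at
  `|k| <= K = 50`; conjugate pairs are combined analytically into real
  terms, so no imaginary round-off can accumulate. The coefficient tail
  decays like `1/k^2`, which is slow exactly at `t = T`; since the mean is
  continuous there (value `n0`, verified against the renewal solver),
  `mean_refractory()` returns `n0` for `t <= T` and uses the sum only for
  `t > T`, where its error at `K = 50` is ~3e-4 relative. An automatic
  `K -> 1.5 K` comparison warns when truncation matters; the warning is
  deliberately conservative just past `t = T`.
- **Lambert W.** No installed R package provides complex branch-`k`
  Lambert W, so `lambert_w()` implements Halley iteration with
  series/asymptotic initial guesses; every pole is certified against the
  characteristic equation `(s + gamma0) e^{sT} = 2 gamma0` to 1e-10
  relative residual (observed ~1e-14).
- **Renewal solver.** `renewal_moments()` discretizes the Volterra
  convolution equations for the per-ancestor mean and second moment with
  the trapezoidal rule (observed second-order convergence). The
  second-moment recursion is formulated for `q = E[n^2] - m`, which makes
  the pre-division variance vanish identically. This solver is the ground
  truth for the non-Markovian variance, replacing a series form that is
  numerically ill-behaved (severe cancellations).
- **Discrete-time simulator bias.** The per-step scheme multiplies the
  mean by `1 + P_sigma - P_kappa` per step rather than `e^{(sigma-kappa)dt}`,
  an O(dt) bias (e.g. -4.3% on the growth-phase mean at `dt = 1`,
  `t = 100`). Tests comparing simulation against closed forms therefore
  use `dt` small enough that the bias is well below Monte-Carlo noise
  (`dt = 0.1` for Markov rates ~0.03; `dt <= 0.01` for refractory runs),
  and the bias convergence under dt-halving is itself asserted against the
  exact event-driven backend. At criticality the per-step mean factor is
  exactly 1, so the homeostatic mean is unbiased at any `dt`.
- **Step resolution and ages.** Within a step, deaths and divisions are
  drawn from the multinomial with the marginal probabilities
  `P_kappa, P_sigma` (identical in law to one uniform per cell with
  death checked first). Refractory eligibility is inclusive (`age >= T`,
  Heaviside `H(0) = 1`); newborns start at age 0 and cannot divide in the
  step that created them; `T` is rounded to a multiple of `dt` with a
  warning. A population cap (default 1e7) aborts runaway growth runs.
- **Seeds.** Per-sample seeds derive from `(seed, sample_id)` via a fixed
  Lehmer-style mix, so ensembles are bit-reproducible and insensitive to
  execution order.

## What the synthetic ensembles do and do not establish

All data in the tests are generated by the package's own simulators under
fixed seeds, at the reference parameters above. A green test establishes
that the simulators, the estimators and the closed forms are mutually
consistent at stated statistical tolerances (2-3 standard errors, with
jackknife errors for correlation estimates, which share samples across
`t2` values). It does not establish anything about real tissues: the
generators inherit the models' idealizations (independence, no space, no
true cell-cycle structure beyond a single refractory delay, no
measurement noise). Estimator choices the source material leaves open -
unbiased (n-1) covariances, jackknife/Wald standard errors, last-third
exponential fit windows, minima-based oscillation detection with a
0.75-rolling-median depth threshold - are documented defaults, not claims.

## Known limitations

- The non-Markovian model has no event-driven backend (the discrete
  simulator with small `dt` plus the renewal oracle fills that role) and
  no apoptosis; clone-size distributions are out of scope.
- Extinction timing is only resolved to the output grid (rounded up to
  the next grid point).
- The finite-time extinction probability `P_0(t)` is not exposed in
  closed form; finite-horizon extinction fractions are validated by
  simulation only.
- `estimate_oscillation_period()` assumes a damped oscillation on an
  exponential trend; it flags, rather than fits, series with fewer than
  two qualifying minima.
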