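# tissuegrowth

Stochastic models of tissue size for theorists and modellers studying
growth, atrophy and homeostasis: how do fluctuations in cell number behave
when every cell independently proliferates and dies, and what changes when
cells must traverse a cell cycle before dividing again?

The package implements, simulates and cross-validates two minimal models:

1. **Markovian birth–death branching process.** Each of `n(t)` cells
   divides with rate σ and dies with rate κ (probabilities per unit time).
   Closed forms implemented:
   - mean `⟨n(t)⟩ = n₀ e^{(σ−κ)t}` (constant `n₀` at σ = κ),
   - variance `Var n(t) = n₀ (σ+κ)/(σ−κ) · e^{(σ−κ)t}(e^{(σ−κ)t} − 1)`
     (`2 n₀ κ t` at σ = κ),
   - extinction probability `P_e = 1` for κ ≥ σ, `(κ/σ)^{n₀}` otherwise,
   - connected correlation `C_c(t₁,t₂) = Var n(t₁) · e^{(σ−κ)(t₂−t₁)}`,
   - Pearson correlation `ρ(t₁,t₂) = C_c/√(Var n(t₁) Var n(t₂))`, which is
     `√(t₁/t₂)` at criticality (power-law decay, exponent 1/2, infinite
     correlation time), and correlation time `1/(κ−σ)` in the decline
     phase.

   Homeostasis (σ = κ) sits between the decline and growth phases as a
   genuinely *critical* state: constant mean, linearly growing variance,
   power-law decorrelation.

2. **Refractory-period (non-Markovian) model.** Pure birth: a cell of age
   τ (time since its last division) divides with rate `γ(τ) = γ₀ H(τ−T)`,
   i.e. division is forbidden during a refractory period `T` — a minimal
   proxy for the cell cycle. The Laplace transform of the mean has poles
   `ŝ_k = −γ₀ + W_k(2Tγ₀ e^{Tγ₀})/T` (Lambert W, branch k). The package
   evaluates the exact pole-expansion mean, the effective Malthusian rate
   `ŝ₀` (so `⟨n(t)⟩ ~ e^{ŝ₀(t−T)}`), the damped-oscillation period
   `T̃ ≈ 2π/Im ŝ₁`, and an independent renewal-equation (Volterra) solver
   for mean *and* variance.

Both models come with discrete-time ensemble simulators (per-step
probabilities `P = 1 − e^{−rate·Δt}`), an exact event-driven backend for
validation, and ensemble estimators (moments, two-time correlations with
jackknife errors, extinction fraction, exponential/power-law/oscillation
fits).

## Worked example

```r
library(tissuegrowth)

r <- markov_rates(sigma = 0.03, kappa = 0.015)   # growth phase
mean_markov(r, n0 = 50, t = 100)        # 224.0845
var_markov(r, n0 = 50, t = 100)         # 2340.577
extinction_probability(r, n0 = 50)      # 8.881784e-16  (~9e-16)

crit <- markov_rates(0.03, 0.03)                 # homeostatic tissue
pearson_correlation_markov(crit, 50, t1 = 25, t2 = 100)   # 0.5 = sqrt(25/100)

cfg <- sim_config("markov", crit, n0 = 50, dt = 1, t_max = 200,
                  n_samples = 300, seed = 1)
mom <- ensemble_moments(simulate_ensemble(cfg))
mom$mean[201]                           # 48.38667 (+- 1.33): mean stays at n0

p <- refractory_params(gamma0 = 1, T = 1)
effective_rate(p)                       # 0.3748225  (Malthusian rate s_0)
mean_refractory(p, n0 = 50, t = 5)      # 251.4294
oscillation_period(refractory_params(10, 1))   # 1.086982 (~T when gamma0*T >> 1)
```

Reading: a growing tissue started from 50 cells has mean 224 and standard
deviation √2341 ≈ 48 cells at t = 100, and essentially never goes extinct
(P_e ≈ 9·10⁻¹⁶). The homeostatic ensemble mean stays at the initial 50
cells while the variance keeps growing. With a refractory period equal to
1/γ₀, the effective long-run growth rate drops from 1 to 0.375.

## Command line

```sh
Rscript inst/scripts/tissuegrowth simulate --model markov --sigma 0.03 \
    --kappa 0.015 --n0 50 --dt 1 --tmax 300 --samples 300 --seed 7 --out ens.csv
Rscript inst/scripts/tissuegrowth analytic --model markov --sigma 0.03 \
    --kappa 0.015 --n0 50 --t 100
Rscript inst/scripts/tissuegrowth poles --gamma0 1 --T 1 --K 3
Rscript inst/scripts/tissuegrowth correlate --in ens.csv --t1 100 --t2 300
Rscript inst/scripts/tissuegrowth reproduce --experiment fig3 --seed 1 \
    --scale 0.25 --out report
```

`reproduce` re-runs the figure-level ensemble experiments (three Markov
phases; critical correlations; refractory slopes) and writes a CSV/JSON
table comparing simulated against live-computed analytic values at 3σ
(4σ for scaled-down runs).

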