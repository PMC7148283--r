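# lbabridge

Bayes factors for linear ballistic accumulator (LBA) models of choice and
response time, computed by Warp-III bridge sampling.

## What problem this solves

Evidence-accumulation models explain a decision as a race between
accumulators, one per response option. In the LBA, an accumulator starts
at a point drawn uniformly on (0, A), gains evidence linearly at a rate
drawn from a zero-truncated normal with mean *v* and SD *s*, and responds
on reaching threshold *b* = *A* + *B*; RT = t0 + winning finishing time.
Researchers comparing LBA variants — "did the manipulation change drift
rates or thresholds?" — need the Bayes factor

BF₁₂ = p(y | M₁) / p(y | M₂),

the ratio of marginal likelihoods p(y | M) = ∫ p(y | θ, M) p(θ | M) dθ.
These integrals are intractable for the LBA and high-dimensional in
hierarchical applications. This package estimates them with **warp bridge
sampling**: posterior draws are transformed to the real line, then warped
to match the first three moments of a standard normal proposal
(mean-centering, covariance-whitening via a Cholesky factor R, and
sign-symmetrization about the mean), and the evidence is the fixed point
of the optimal-bridge updating scheme

p̂⁽ᵗ⁺¹⁾ = [ (1/N₂) Σᵢ l₂ᵢ / (s₁ l₂ᵢ + s₂ p̂⁽ᵗ⁾) ] /
         [ (1/N₁) Σⱼ 1 / (s₁ l₁ⱼ + s₂ p̂⁽ᵗ⁾) ],

with Warp-III heights l₁ⱼ = (|R|/2) [q(2μ − θ*ⱼ) + q(θ*ⱼ)] / g(R⁻¹(θ*ⱼ − μ))
over posterior draws θ*, and l₂ᵢ defined analogously over standard-normal
proposal draws mapped through μ ± Rθ̃. Everything runs on the log scale;
the weights use a conservative effective sample size.

The package provides, end to end:

- `lba_pdf()` / `lba_cdf()` / `dlba_race()` / `simulate_race()` — the LBA
  finishing-time distributions, defective race density and simulator;
- `lba_design()` / `single_design()` / `hier_design()` — declarative
  model designs (full/restricted; V-, 0-, B- and restricted-B hierarchical
  models) with truncated-normal priors and zero-bounded group-level
  distributions;
- `run_de_mcmc()` / `run_de_mcmc_hier()` / `fit_lba()` — differential
  evolution MCMC (crossover + burn-in migration + unstuck repair),
  split-chain `rhat()` and autocorrelation `ess()`;
- `warp_marglik()` (Warp-0/I/II/III), `simple_mc_marglik()`,
  `savage_dickey_logbf()`, `bayes_factor()`, `repeat_estimates()`;
- `run_study1()` / `run_study2()` / `run_study3()` — seeded replication
  drivers for the nested single-participant comparison, the hierarchical
  nested/non-nested comparisons, and the equivocal hierarchical
  comparison;
- a thin CLI (`inst/cli/lbabridge.R`) with `simulate`, `fit`, `marglik`,
  `bf` and `study` subcommands.

## Worked example

Simulate the canonical single-participant dataset (500 trials from the
full model at A = 0.5, B = 1, v_true = 4, v_false = 3, t0 = 0.2), fit the
full model and a restricted model that fixes v_true = 3.55, and compare
them:

```r
library(lbabridge)
set.seed(2026)
full       <- single_design("full")
restricted <- single_design("restricted")      # v_true fixed at 3.55
trials <- simulate_design(full, study1_generating_values(), 250)

cfg   <- de_config(n_retained = 2000)
fit_f <- fit_lba(full, trials, cfg, seed = 11)
fit_f
#> LBA posterior samples: 15 chains x 134 iterations x 5 parameters
#> parameters: A, B, v_true, v_false, t0
#> max split R-hat: 1.019

ml_f <- single_marglik(full, trials, fit_f)
ml_f
#> log marginal likelihood: 311.5894 (Warp-III)
#>   iterations 9, converged TRUE, N1 = 1005, N2 = 1005, ESS = 404

fit_r <- fit_lba(restricted, trials, cfg, seed = 12)
ml_r  <- single_marglik(restricted, trials, fit_r)
bayes_factor(ml_f, ml_r)
#> log BF = -1.5610 (BF = 0.2099)

round(colMeans(pool_draws(fit_f)), 3)
#>       A       B  v_true v_false      t0
#>   0.769   0.674   4.025   2.840   0.253
```

Reading the output: the sampler mixed (split R-hat ≈ 1.02, well under the
1.05 single-participant standard), the bridge iteration converged in 9
steps, and the log Bayes factor is near zero — the restricted model's
slight misspecification (3.55 vs. the generating 4) is roughly balanced
by its parsimony advantage, so the evidence is close to equivocal; the
exact balance point moves with the simulated dataset. Posterior means sit
near the generating values (drift rates ≈ 4 and ≈ 3, t0 ≈ 0.25 s).
Because bridge estimates are stochastic, conclusions should rest on
repeated runs: `repeat_estimates()` reports the median and range over
independent repetitions with fresh posterior samples.

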