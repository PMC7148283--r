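---
title: "Marginal likelihoods for LBA models by warp bridge sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal likelihoods for LBA models by warp bridge sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lbabridge)
```

# The problem

Choice–response-time experiments are routinely modelled with evidence-
accumulation models, and the linear ballistic accumulator (LBA) is one of
the two standard choices. Comparing LBA variants — does a manipulation act
on drift rates or on thresholds? — calls for Bayes factors, i.e. ratios of
marginal likelihoods

$$ p(y \mid \mathcal{M}) = \int p(y \mid \theta, \mathcal{M})\,
   p(\theta \mid \mathcal{M})\, d\theta, $$

which are analytically intractable for the LBA and, in hierarchical form,
high-dimensional. `lbabridge` implements the full pipeline: the LBA
likelihood and simulator, single-participant and hierarchical model
specifications with truncated-normal priors, a differential-evolution MCMC
(DE-MCMC) posterior sampler, and warp bridge sampling for the evidence,
alongside two comparison estimators (simple Monte Carlo and the
Savage–Dickey density ratio).

# The LBA race model

Each response option has one accumulator. On a trial, accumulator $i$
starts at a point drawn uniformly on $(0, A)$, accumulates evidence
linearly at a rate drawn from a normal distribution with mean $v_i$ and
standard deviation $s_i$ truncated below at zero, and triggers its
response on reaching threshold $b = A + B$ ($B > 0$ is the gap between
threshold and the top of the start-point range). The observed response is
the winner and RT $= t_0 + $ winning finishing time, with $t_0$ the
non-decision time in seconds.

The finishing-time distribution of a single accumulator has the standard
closed form in terms of $z_1 = (b - A - tv)/(ts)$ and
$z_2 = (b - tv)/(ts)$,

$$ F(t) = 1 + \tfrac{b-A-tv}{A}\Phi(z_1) - \tfrac{b-tv}{A}\Phi(z_2)
   + \tfrac{ts}{A}\{\phi(z_1) - \phi(z_2)\}, $$
$$ f(t) = \tfrac{1}{A}\{-v\Phi(z_1) + s\phi(z_1) + v\Phi(z_2) -
   s\phi(z_2)\}, $$

both divided by $\Phi(v/s)$ because the rate distribution is truncated
below at zero independently per accumulator; with that truncation every
accumulator finishes and $F \to 1$. For $A < 10^{-6}$ the package switches
to the deterministic-start form $F(t) = \Phi((v - b/t)/s)/\Phi(v/s)$,
avoiding the $1/A$ expressions. The joint "defective" density of
(response, RT) is the winner's density times the survival functions of the
losers at decision time $t = \mathrm{RT} - t_0$; it is $-\infty$ on the
log scale for $\mathrm{RT} \le t_0$ (a structural zero) and otherwise
floored at $e^{-700}$ so that legal but extreme observations do not
destroy a likelihood sum by underflow. Both closed forms are validated in
the test suite against direct simulation of the generative story and
against quadrature.

# Designs and priors

A design maps a named parameter vector to per-cell race parameters: the
accumulator matching the stimulus receives $(v_\mathrm{true},
s_\mathrm{true})$, the other $(v_\mathrm{false}, s_\mathrm{false})$.
Exactly one parameter may vary across the two conditions, giving the
V-model (matching drift rate varies), the B-model (threshold gap varies)
and the 0-model (neither). Restricted models are expressed as *constants*
in the design — e.g. the single-participant restricted model fixes
$v_\mathrm{true} = 3.55$ and carries no prior for it — rather than as
degenerate priors.

Single-participant priors are independent truncated normals:
$A, B \sim \mathcal{N}_+(1,1)$, $v_\mathrm{true} \sim \mathcal{N}(2,3^2)$,
$v_\mathrm{false} \sim \mathcal{N}(1,3^2)$,
$t_0 \sim \mathcal{N}_{(0.1,\infty)}(0.3, 0.25^2)$. In the
single-participant study both drift-rate SDs are fixed to 1; hierarchical
models fix only $s_\mathrm{true} = 1$ and treat $s_\mathrm{false}$ as a
free participant-level parameter — the minimum identifying restriction.

Hierarchically, participant-level parameters are independent draws from
zero-bounded normal group distributions with location $\mu_p$ and scale
$\sigma_p$, and each $(\mu_p, \sigma_p)$ carries a zero-bounded normal
hyperprior: $(1,1)$ for $A$, $(0.4, 0.4^2)$ for $B$, $(3, 3^2)$ for
$v_\mathrm{true}$, $(1,1)$ for $v_\mathrm{false}$ and
$s_\mathrm{false}$, and $(0.3, 0.3^2)$ for $t_0$. The zero bound on the
group distributions applies to *all* participant-level parameters,
including $t_0$; the 0.1-second lower bound belongs only to the
single-participant prior. Participants are conditionally independent given
the group level, and group distributions are independent across parameters
(no group-level covariance) — a deliberate scope restriction.

The synthetic-data generator draws participant parameters from these group
distributions with $\sigma_p = \mu_p / 10$ by default ("appreciable but
not excessive" individual differences) and simulates $k$ trials per
(condition × stimulus) cell. Generating group locations for the three
hierarchical generators are: V-model $\mu_A = 1$, $\mu_B = 0.4$,
$\mu_{v^{(1)}_\mathrm{true}} = 4$, $\mu_{v^{(2)}_\mathrm{true}} = 3$,
$\mu_{v_\mathrm{false}} = \mu_{s_\mathrm{false}} = 1$, $\mu_{t_0} = 0.3$;
0-model the same with a single $\mu_{v_\mathrm{true}} = 3$; B-model
$\mu_{B^{(1)}} = 0.3$, $\mu_{B^{(2)}} = 0.7$,
$\mu_{v_\mathrm{true}} = 3.5$, the rest as above. The single-participant
generator uses $A = 0.5$, $B = 1$, $v_\mathrm{true} = 4$,
$v_\mathrm{false} = 3$, $t_0 = 0.2$ with 250 trials per stimulus. What the
generator emulates is exactly this parametric story; it does **not**
emulate contaminant responses, trial-level non-decision-time variability,
sequential effects, or parameter drift, so passing tests demonstrate
correctness of the estimator under the model, not robustness of the model
to real data.

# DE-MCMC

LBA posteriors are strongly correlated, so proposals are scaled differences
of other chains' states: chain $i$ proposes
$\theta_i + \gamma(\theta_j - \theta_k) + \epsilon$ with distinct random
$j, k$, $\gamma = 2.38/\sqrt{2d}$ and uniform jitter of half-width 0.001,
accepted by the Metropolis rule. Chains number three times the parameter
count (participant-level parameter count in the hierarchical sampler) and
are thinned by 10. During burn-in only, two repair mechanisms run: with
probability 5% per iteration a *migration* step lets a random cycle of
chains (uniform size between 2 and the chain count) propose adopting their
predecessor's state, and after each burn-in chunk chains whose mean log
posterior lags the chain median by more than a configurable gap (default
30) are restarted from a healthy chain. Burn-in proceeds in chunks of 100
iterations and ends when the split R-hat over the last chunk falls below
1.1 (with a chunk cap); the sampling phase is crossover-only. The
hierarchical sampler updates blocks: each participant's parameters by
crossover conditional on that chain's group parameters (one likelihood
evaluation per chain per participant), then the group block conditional on
the participant parameters, which needs no likelihood evaluations.

Diagnostics are split-chain R-hat and an autocorrelation-based effective
sample size (Geyer's initial monotone positive-pair sequence, summed over
chains). Sampler correctness is tested on targets with known moments and
by parameter recovery on simulated data.

# Warp bridge sampling

Bridge sampling rests on the identity
$p(y) = \mathbb{E}_g[hq]/\mathbb{E}_\mathrm{post}[hg]$ for a proposal $g$
and bridge function $h$; with the optimal $h$ the estimate is the fixed
point of the updating scheme

$$ \hat p^{(t+1)} = \frac{\frac{1}{N_2}\sum_i l_{2,i}\,/\,(s_1 l_{2,i} +
   s_2 \hat p^{(t)})}{\frac{1}{N_1}\sum_j 1\,/\,(s_1 l_{1,j} + s_2 \hat
   p^{(t)})}. $$

The proposal is a standard normal; *warping* transforms the posterior
draws to match its moments — mean (Warp-I), mean and covariance (Warp-II),
and additionally symmetry (Warp-III), which mixes each draw with its
reflection $2\mu - \theta^\ast$ and gives, with $\Sigma = RR^\top$ from a
Cholesky factorization,

$$ l_{1,j} = \frac{|R|}{2}\,\frac{q(2\mu - \theta^\ast_j) +
   q(\theta^\ast_j)}{g(R^{-1}(\theta^\ast_j - \mu))}, \qquad
   l_{2,i} = \frac{|R|}{2}\,\frac{q(\mu - R\tilde\theta_i) + q(\mu +
   R\tilde\theta_i)}{g(\tilde\theta_i)}. $$

Warp-III doubles the posterior-density evaluations relative to Warp-II but
is never less precise, and is markedly better when the (transformed)
posterior is skewed — typical with few observations.

Implementation decisions, all of which are configurable:

* **Bounded parameters** are first transformed componentwise to the real
  line: identity (unbounded), $\log(\theta - l)$ (lower-bounded),
  $\log(u - \theta)$ (upper-bounded), probit
  $\Phi^{-1}((\theta - l)/(u - l))$ (double-bounded), with the matching
  log-Jacobian added to the natural-scale log posterior. Drift-rate means
  are unbounded and pass through untouched.
* **Half-splitting** is per chain by iteration order; the pooled first
  halves estimate $\mu$ and $R$, the pooled second halves enter the
  updating scheme. $N_2$ (proposal draws) defaults to the size of the
  second half.
* **Weights** $s_1, s_2$ use a conservative effective sample size — the
  minimum across parameters of the second half's ESS — in place of $N_1$,
  because the optimal bridge function assumes i.i.d. posterior draws;
  $N_1$ itself stays the draw count in the averages.
* **All arithmetic is in log space**, with a single shift constant (the
  median of $\log l_2$) stabilizing the scheme; the initial guess is 0 on
  the log scale, convergence is declared at relative change
  $\le 10^{-10}$, and the iteration cap is 1000. On the models studied
  here the scheme converges in well under 30 iterations.
* **Oscillation restart**: in rare cases the scheme stalls in a period-2
  alternation between two values; this is detected from the trace and the
  scheme is restarted once from their geometric mean (arithmetic mean on
  the log scale). A failure with no detectable oscillation raises an
  error carrying the trace.
* Estimates should always be *repeated* (fresh posterior samples and
  proposal draws per repetition) and summarized by median and range;
  `repeat_estimates()` wires this up. Approximate single-run error
  formulas are deliberately not provided.

The simple Monte Carlo estimator (likelihood averaged over prior draws)
and the Savage–Dickey ratio (posterior/prior density at a nested test
value, Gaussian kernel with Sheather–Jones plug-in bandwidth, falling back
to Silverman's rule) are included as baselines; both are cross-checked
against closed forms in the tests, and the bridge estimator is validated
against a conjugate normal–normal model where the evidence is available
analytically.

# Problem sizes used in the tests

The full-scale hierarchical studies (20 participants × 200 trials per
cell, or 80 × 50, with around $10^5$ retained draws) take hours on one
CPU. The shipped tests run the same code paths at desk scale, chosen to
finish in minutes while preserving the qualitative findings: the
single-participant comparison uses the full 500-trial dataset with 5,000
retained draws and five independent fit-plus-bridge repetitions; the
hierarchical comparisons use 8 participants × 50 trials per cell with
2,000 retained draws. At these sizes the single-participant log Bayes
factor (full vs. restricted) is indifferent (median within ±1 of 0 — the
dataset itself varies with the seed, so the balance point does too), the
hierarchical threshold comparison yields finite, stable Bayes factors
with overlapping repetition ranges across warp levels, and nested
comparisons favor the data-generating model. Direction-of-evidence, not
magnitude, is the replication claim at desk scale: figure-scale log-BF
magnitudes require the full-scale runs via `run_study2()` /
`run_study3()` defaults.

Two points the design leaves open are resolved as follows. The
single-participant study fixes both drift-rate SDs to 1 (its design
constants), while hierarchical models fix only $s_\mathrm{true}$; study
configurations carry this choice explicitly. And the hierarchical design
sizes are taken at face value as $n \times k \times 4$ cells trials
(e.g. 20 × 200 × 4 = 16,000 trials); the generator exposes $n$, $k$ and
the cell count directly.

# Known limitations

* The likelihood is pure R; it is vectorized per design cell and fast
  enough for the shipped studies, but an order of magnitude slower than a
  compiled implementation would be.
* Migration internals (cycle construction, subset-size distribution) are
  a reasonable standard variant, not a bit-for-bit reproduction of any
  particular sampler release; stationarity is what the tests pin down.
* Only LBA race likelihoods are provided — no diffusion-model or
  lognormal-race families — and no trial-level variability in $t_0$.
* The Savage–Dickey estimator requires nesting and a well-covered test
  value; it warns when the test value leaves the central 99% of the
  draws.
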