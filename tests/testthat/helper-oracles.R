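# Shared oracles and fixtures built in code.

# Closed-form log marginal likelihood of the conjugate normal-normal model:
# y_i ~ N(theta, sigma^2) with known sigma, theta ~ N(mu0, tau0^2).
conjugate_logml <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  ybar <- mean(y)
  -n / 2 * log(2 * pi * sigma^2) - 0.5 * log(1 + n * tau0^2 / sigma^2) -
    sum((y - ybar)^2) / (2 * sigma^2) -
    n * (ybar - mu0)^2 / (2 * (sigma^2 + n * tau0^2))
}

# Build an lba_samples object from exact iid posterior draws of the
# conjugate model, arranged as 3 chains.
conjugate_fixture <- function(n_obs = 50, n_draws = 9999, seed = 1,
                              sigma = 1.3, mu0 = 0.5, tau0 = 2,
                              theta_true = 1.2) {
  set.seed(seed)
  y <- rnorm(n_obs, theta_true, sigma)
  pv <- 1 / (1 / tau0^2 + n_obs / sigma^2)
  pm <- pv * (mu0 / tau0^2 + n_obs * mean(y) / sigma^2)
  per_chain <- ceiling(n_draws / 3)
  draws <- array(rnorm(3 * per_chain, pm, sqrt(pv)), c(3, per_chain, 1),
                 dimnames = list(NULL, NULL, "theta"))
  log_q <- function(x) {
    th <- x[, 1]
    vapply(th, function(t)
      sum(dnorm(y, t, sigma, log = TRUE)) + dnorm(t, mu0, tau0, log = TRUE),
      numeric(1))
  }
  list(y = y, sigma = sigma, mu0 = mu0, tau0 = tau0,
       post_mean = pm, post_var = pv,
       samples = lba_samples(draws),
       log_q = log_q,
       bounds = list(lower = -Inf, upper = Inf),
       logml = conjugate_logml(y, sigma, mu0, tau0))
}

# Skewed 1-D target with known normalizing constant: unnormalized
# q(theta) = theta^(a-1) exp(-b theta) on theta > 0, integral Gamma(a)/b^a.
# "Prior" Exp(1) and "likelihood" q/prior give a factorization for simple
# Monte Carlo.
gamma_fixture <- function(a = 2, b = 2) {
  list(a = a, b = b,
       logml = lgamma(a) - a * log(b),
       log_q = function(x) {
         th <- x[, 1]
         out <- rep(-Inf, length(th))
         pos <- th > 0
         out[pos] <- (a - 1) * log(th[pos]) - b * th[pos]
         out
       },
       draw_samples = function(n_draws, chains = 3) {
         per_chain <- ceiling(n_draws / chains)
         lba_samples(array(rgamma(chains * per_chain, a, b),
                           c(chains, per_chain, 1),
                           dimnames = list(NULL, NULL, "theta")))
       },
       bounds = list(lower = 0, upper = Inf))
}

# --- memoized expensive fixtures (shared across acceptance checks) --------
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Single-participant nested comparison: one 500-trial dataset from the full
# model; per repetition a fresh DE-MCMC fit of both models and a Warp-III
# bridge for each, at 5000 retained draws.
study1_fixture <- function() {
  memo("study1", function() {
    seed <- 20260926L
    set.seed(seed)
    full <- single_design("full")
    restricted <- single_design("restricted")
    trials <- simulate_design(full, study1_generating_values(), 250)
    cfg <- de_config(n_retained = 5000)
    reps <- 5
    fits_full <- vector("list", reps)
    ml_full <- vector("list", reps)
    ml_res <- vector("list", reps)
    log_bf <- numeric(reps)
    for (r in seq_len(reps)) {
      sf <- fit_lba(full, trials, cfg, seed = seed + 101L * r)
      sr <- fit_lba(restricted, trials, cfg, seed = seed + 101L * r + 1L)
      mf <- single_marglik(full, trials, sf)
      mr <- single_marglik(restricted, trials, sr)
      fits_full[[r]] <- sf
      ml_full[[r]] <- mf
      ml_res[[r]] <- mr
      log_bf[r] <- bayes_factor(mf, mr)$log_bf
    }
    list(seed = seed, trials = trials, full = full, restricted = restricted,
         fits_full = fits_full, ml_full = ml_full, ml_res = ml_res,
         log_bf = log_bf)
  })
}

# Scaled hierarchical comparison: one dataset from the B-model (n = 8
# participants, k = 50 trials per cell), one fit of the B- and restricted
# B-models, and repeated bridge estimates at warp levels 2 and 3.
hierB_fixture <- function() {
  memo("hierB", function() {
    seed <- 42L
    bmod <- hier_design("B")
    bres <- hier_design("B_res")
    set.seed(seed)
    dat <- generate_hier_dataset(bmod, n = 8, k = 50)
    cfg <- de_config(n_retained = 2000, max_burn_chunks = 8)
    s_b <- run_de_mcmc_hier(bmod, dat$trials, cfg, seed = seed + 1L)
    s_r <- run_de_mcmc_hier(bres, dat$trials, cfg, seed = seed + 2L)
    bf_reps <- function(level, reps = 2) {
      vapply(seq_len(reps), function(r) {
        set.seed(seed + 100L * level + r)
        ml_b <- suppressWarnings(hier_marglik(bmod, dat$trials, s_b,
                                              level = level))
        ml_r <- suppressWarnings(hier_marglik(bres, dat$trials, s_r,
                                              level = level))
        bayes_factor(ml_b, ml_r)$bf
      }, numeric(1))
    }
    list(seed = seed, dat = dat, bmod = bmod, bres = bres,
         samples_b = s_b, samples_r = s_r,
         bf_w3 = bf_reps(3), bf_w2 = bf_reps(2))
  })
}
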