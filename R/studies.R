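# Seeded replication drivers for the three simulation studies, plus
# convenience glue between models, samplers and the bridge estimator.

#' Warp bridge marginal likelihood for a single-participant model
#'
#' @param design an [lba_design()] with prior.
#' @param trials trial table the samples were fit to.
#' @param samples an [lba_samples()] object from [fit_lba()].
#' @param level warp level.
#' @param ... passed to [warp_marglik()].
#' @return an \code{"lba_marglik"} result.
#' @export
single_marglik <- function(design, trials, samples, level = 3, ...) {
  warp_marglik(samples, log_posterior_single(design, trials),
               prior_bounds(design$prior), level = level, ...)
}

#' Warp bridge marginal likelihood for a hierarchical model
#'
#' @param hier an [hier_design()].
#' @param trials trial table covering all subjects.
#' @param samples an [lba_samples()] object from [run_de_mcmc_hier()].
#' @param level warp level.
#' @param ... passed to [warp_marglik()].
#' @return an \code{"lba_marglik"} result.
#' @export
hier_marglik <- function(hier, trials, samples, level = 3, ...) {
  warp_marglik(samples, log_posterior_hier(hier, trials),
               hier_bounds(hier, samples$subjects), level = level, ...)
}

#' Single-participant nested-comparison study
#'
#' Simulates one dataset from the full model (A = 0.5, B = 1, v_true = 4,
#' v_false = 3, t0 = 0.2; 250 trials per stimulus by default), then
#' repeatedly fits the full and the restricted (v_true = 3.55) model and
#' estimates the log Bayes factor in favor of the full model with Warp-III
#' bridge sampling, simple Monte Carlo (an order of magnitude more draws),
#' and the Savage-Dickey density ratio, over a grid of sample sizes.
#'
#' @param seed integer seed; the dataset and every repetition derive from it.
#' @param n_per_stimulus trials per stimulus.
#' @param grid increasing vector of pooled posterior sample sizes.
#' @param repetitions independent repetitions per estimator and grid point
#'   (fresh posterior samples each).
#' @param mc_factor simple Monte Carlo uses \code{mc_factor * grid} prior
#'   draws.
#' @param config sampler configuration template; \code{n_retained} is
#'   overridden by \code{max(grid)}.
#' @return data frame (estimator, n_samples, repetition, log_bf) with a
#'   \code{"summary"} attribute of medians and ranges.
#' @export
run_study1 <- function(seed = 1, n_per_stimulus = 250,
                       grid = c(1000, 2000, 5000), repetitions = 3,
                       mc_factor = 10, config = de_config()) {
  stopifnot(all(diff(grid) > 0))
  set.seed(seed)
  full <- single_design("full")
  restricted <- single_design("restricted")
  theta_gen <- study1_generating_values()
  trials <- simulate_design(full, theta_gen, n_per_stimulus)
  config$n_retained <- max(grid)
  lq_full <- log_posterior_single(full, trials)
  lq_res <- log_posterior_single(restricted, trials)

  rows <- list()
  add <- function(est, g, r, lbf)
    rows[[length(rows) + 1L]] <<- data.frame(estimator = est, n_samples = g,
                                             repetition = r, log_bf = lbf)
  for (r in seq_len(repetitions)) {
    sf <- fit_lba(full, trials, config, seed = seed + 101L * r)
    sr <- fit_lba(restricted, trials, config, seed = seed + 101L * r + 1L)
    for (g in grid) {
      mlf <- single_marglik(full, trials, head_samples(sf, g))
      mlr <- single_marglik(restricted, trials, head_samples(sr, g))
      add("warp3", g, r, bayes_factor(mlf, mlr)$log_bf)
      # simple Monte Carlo over prior draws
      compiled_f <- compile_trials(full, trials)
      compiled_r <- compile_trials(restricted, trials)
      llf <- function(x) apply(x, 1, function(th)
        loglik_compiled(full, compiled_f, stats::setNames(th, full$pars)))
      llr <- function(x) apply(x, 1, function(th)
        loglik_compiled(restricted, compiled_r,
                        stats::setNames(th, restricted$pars)))
      mc_f <- simple_mc_marglik(llf, full$prior, mc_factor * g)
      mc_r <- simple_mc_marglik(llr, restricted$prior, mc_factor * g)
      add("simple_mc", g, r, bayes_factor(mc_f, mc_r)$log_bf)
      # Savage-Dickey on v_true at the restricted value
      vt <- pool_draws(head_samples(sf, g))[, "v_true"]
      lbf01 <- savage_dickey_logbf(vt, dnorm(3.55, 2, 3, log = TRUE), 3.55)
      add("savage_dickey", g, r, -lbf01)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(
    log_bf ~ estimator + n_samples, out,
    function(v) c(median = stats::median(v), min = min(v), max = max(v)))
  out
}

#' Hierarchical model-comparison study
#'
#' For each requested (generator, alternative) pair, simulates one
#' hierarchical dataset from the generator (group scales = locations / 10),
#' fits both models with the blocked DE-MCMC sampler, and estimates the
#' Warp-III log Bayes factor in favor of the generator, repeated with fresh
#' posterior samples.
#'
#' @param comparisons list of length-2 character vectors
#'   \code{c(generator, alternative)} from \code{"V"}, \code{"0"},
#'   \code{"B"}.
#' @param n participants; \code{n = 20, k = 200} and \code{n = 80, k = 50}
#'   are the two study regimes.
#' @param k trials per design cell.
#' @param repetitions independent fit + bridge repetitions.
#' @param seed integer seed.
#' @param config sampler configuration.
#' @return data frame (generator, alternative, n, k, repetition, log_bf).
#' @export
run_study2 <- function(comparisons = list(c("V", "0"), c("0", "V"),
                                          c("B", "V"), c("V", "B")),
                       n = 20, k = 200, repetitions = 3, seed = 1,
                       config = de_config()) {
  rows <- list()
  for (ci in seq_along(comparisons)) {
    gen_name <- comparisons[[ci]][1]
    alt_name <- comparisons[[ci]][2]
    gen <- hier_design(gen_name)
    alt <- hier_design(alt_name)
    set.seed(seed + 977L * ci)
    dat <- generate_hier_dataset(gen, n, k)
    for (r in seq_len(repetitions)) {
      s_gen <- run_de_mcmc_hier(gen, dat$trials, config,
                                seed = seed + 977L * ci + 13L * r)
      s_alt <- run_de_mcmc_hier(alt, dat$trials, config,
                                seed = seed + 977L * ci + 13L * r + 7L)
      ml_gen <- hier_marglik(gen, dat$trials, s_gen)
      ml_alt <- hier_marglik(alt, dat$trials, s_alt)
      rows[[length(rows) + 1L]] <-
        data.frame(generator = gen_name, alternative = alt_name,
                   n = n, k = k, repetition = r,
                   log_bf = bayes_factor(ml_gen, ml_alt)$log_bf)
    }
  }
  do.call(rbind, rows)
}

#' Equivocal hierarchical Bayes factor study
#'
#' Generates (or reuses) a dataset from the B-model and compares it to the
#' restricted B-model whose group-level v_false location is fixed to 1.24.
#' Reported on the Bayes factor scale (not log).
#'
#' @param n,k design size; the full-scale study uses n = 20, k = 200.
#' @param repetitions bridge repetitions (fresh posterior samples each).
#' @param seed integer seed.
#' @param config sampler configuration.
#' @param trials optional pre-generated B-model trial table to reuse.
#' @return data frame (repetition, bf) with a \code{"summary"} attribute
#'   (median and range of BF).
#' @export
run_study3 <- function(n = 20, k = 200, repetitions = 3, seed = 1,
                       config = de_config(), trials = NULL) {
  bmod <- hier_design("B")
  bres <- hier_design("B_res")
  if (is.null(trials)) {
    set.seed(seed)
    trials <- generate_hier_dataset(bmod, n, k)$trials
  }
  bf <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    s_b <- run_de_mcmc_hier(bmod, trials, config, seed = seed + 31L * r)
    s_r <- run_de_mcmc_hier(bres, trials, config,
                            seed = seed + 31L * r + 17L)
    ml_b <- hier_marglik(bmod, trials, s_b)
    ml_r <- hier_marglik(bres, trials, s_r)
    bf[r] <- bayes_factor(ml_b, ml_r)$bf
  }
  out <- data.frame(repetition = seq_len(repetitions), bf = bf)
  attr(out, "summary") <- c(median = stats::median(bf), min = min(bf),
                            max = max(bf))
  out
}

#' Write a result object as versioned JSON
#'
#' @param x a list or data frame of results.
#' @param path output path.
#' @export
write_result <- function(x, path) {
  payload <- list(schema_version = 1L, result = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
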