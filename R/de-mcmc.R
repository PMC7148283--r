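# Differential-evolution MCMC: population sampler whose proposals are
# scaled differences of other chains' states, suited to the strongly
# correlated posteriors of accumulator models.  Burn-in mixes crossover
# with occasional migration (cycle swaps) and unstuck replacement; the
# sampling phase is crossover-only with thinning.

#' Sampler configuration
#'
#' @param n_chains number of chains; defaults to 3x the dimension when NULL.
#' @param n_retained total retained draws pooled across chains.
#' @param thin keep every thin-th iteration in the sampling phase.
#' @param migration_prob probability of a migration step per burn-in
#'   iteration (migration is never used after burn-in).
#' @param gamma DE step size; defaults to 2.38 / sqrt(2 d).
#' @param jitter half-width of the uniform jitter added to proposals.
#' @param burn_chunk burn-in proceeds in chunks of this many iterations.
#' @param max_burn_chunks cap on burn-in chunks.
#' @param rhat_threshold burn-in ends early once the max split R-hat over
#'   the last chunk drops below this.
#' @param unstuck_gap during burn-in, chains whose mean log posterior lags
#'   the chain median by more than this are restarted from a healthy chain.
#' @return list of class \code{"de_config"}.
#' @export
de_config <- function(n_chains = NULL, n_retained = 5000, thin = 10,
                      migration_prob = 0.05, gamma = NULL, jitter = 0.001,
                      burn_chunk = 100, max_burn_chunks = 15,
                      rhat_threshold = 1.1, unstuck_gap = 30) {
  stopifnot(thin >= 1, migration_prob >= 0, migration_prob <= 1)
  structure(list(n_chains = n_chains, n_retained = n_retained, thin = thin,
                 migration_prob = migration_prob, gamma = gamma,
                 jitter = jitter, burn_chunk = burn_chunk,
                 max_burn_chunks = max_burn_chunks,
                 rhat_threshold = rhat_threshold,
                 unstuck_gap = unstuck_gap),
            class = "de_config")
}

#' One crossover sweep over all chains
#'
#' Each chain proposes state + gamma * (state_j - state_k) + jitter with
#' distinct random j, k (both different from the chain itself) and accepts
#' by the Metropolis rule on the target log density.  All chains propose
#' against the pre-sweep population.
#'
#' @param state matrix (chains x d) of current states.
#' @param lq vector of current log target values.
#' @param log_q target log density, mapping a matrix of rows to a vector.
#' @param gamma,jitter DE tuning constants.
#' @return list with updated \code{state} and \code{lq}.
#' @export
crossover_step <- function(state, lq, log_q, gamma, jitter) {
  nc <- nrow(state); d <- ncol(state)
  if (nc < 4) stop("crossover needs at least 4 chains")
  jk <- vapply(seq_len(nc), function(i) sample(seq_len(nc)[-i], 2L),
               integer(2))
  prop <- state + gamma * (state[jk[1, ], , drop = FALSE] -
                             state[jk[2, ], , drop = FALSE]) +
    matrix(runif(nc * d, -jitter, jitter), nc, d)
  lqp <- eval_logq(log_q, prop)
  acc <- log(runif(nc)) < (lqp - lq)
  acc[!is.finite(lqp)] <- FALSE
  state[acc, ] <- prop[acc, , drop = FALSE]
  lq[acc] <- lqp[acc]
  list(state = state, lq = lq, accepted = acc)
}

#' One migration step (cycle swap)
#'
#' A random subset of chains forms a cycle; each proposes to adopt its
#' predecessor's state and accepts by the Metropolis rule.  Used during
#' burn-in only, to pull outlying chains into the bulk.
#'
#' @inheritParams crossover_step
#' @return list with updated \code{state} and \code{lq}.
#' @export
migrate_step <- function(state, lq) {
  nc <- nrow(state)
  if (nc < 2) return(list(state = state, lq = lq))
  size <- sample(2:nc, 1L)
  cyc <- sample(seq_len(nc), size)
  pred <- c(cyc[size], cyc[-size])   # predecessor in the cycle
  old_state <- state; old_lq <- lq
  for (m in seq_len(size)) {
    i <- cyc[m]; p <- pred[m]
    if (log(runif(1)) < (old_lq[p] - lq[i])) {
      state[i, ] <- old_state[p, ]
      lq[i] <- old_lq[p]
    }
  }
  list(state = state, lq = lq)
}

replace_stuck <- function(state, lq, gap) {
  med <- stats::median(lq)
  stuck <- which(lq < med - gap)
  if (length(stuck) && length(stuck) < nrow(state)) {
    good <- setdiff(seq_len(nrow(state)), stuck)
    donor <- sample(good, length(stuck), replace = TRUE)
    state[stuck, ] <- state[donor, , drop = FALSE]
    lq[stuck] <- lq[donor]
  }
  list(state = state, lq = lq)
}

init_population <- function(log_q, init, n_chains, d, max_tries = 50) {
  state <- matrix(NA_real_, n_chains, d)
  lq <- rep(-Inf, n_chains)
  for (try in seq_len(max_tries)) {
    bad <- which(!is.finite(lq))
    if (!length(bad)) break
    draws <- init(length(bad))
    if (!is.matrix(draws)) draws <- matrix(draws, nrow = length(bad))
    state[bad, ] <- draws
    lq[bad] <- eval_logq(log_q, draws)
  }
  if (any(!is.finite(lq)))
    stop("could not initialize all chains at a finite log posterior")
  list(state = state, lq = lq)
}

#' Run the DE-MCMC sampler
#'
#' Burn-in proceeds in chunks: crossover with probabilistic migration and
#' unstuck replacement, ending when the split R-hat over the last chunk
#' falls below the threshold or the chunk cap is reached.  The sampling
#' phase is crossover-only and retains every thin-th iteration.
#'
#' @param log_q un-normalized natural-scale log posterior; must map a
#'   matrix of parameter rows to a vector.
#' @param pars parameter names (their number sets the dimension).
#' @param init function(n) returning n over-dispersed start rows (typically
#'   prior draws).
#' @param config a [de_config()].
#' @param seed optional integer seed set before sampling.
#' @return an [lba_samples()] object with per-parameter split R-hat in
#'   \code{$rhat}.
#' @export
run_de_mcmc <- function(log_q, pars, init, config = de_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(pars)
  nc <- config$n_chains %||% max(3 * d, 4)
  if (nc < max(4, d + 1)) stop("need at least max(4, d + 1) chains")
  gamma <- config$gamma %||% (2.38 / sqrt(2 * d))
  pop <- init_population(log_q, init, nc, d)
  state <- pop$state; lq <- pop$lq

  # burn-in
  for (chunk in seq_len(config$max_burn_chunks)) {
    hist <- array(NA_real_, c(nc, config$burn_chunk, d))
    for (it in seq_len(config$burn_chunk)) {
      if (runif(1) < config$migration_prob) {
        mig <- migrate_step(state, lq)
        state <- mig$state; lq <- mig$lq
      }
      cx <- crossover_step(state, lq, log_q, gamma, config$jitter)
      state <- cx$state; lq <- cx$lq
      hist[, it, ] <- state
    }
    rs <- replace_stuck(state, lq, config$unstuck_gap)
    moved <- !identical(rs$lq, lq)
    state <- rs$state; lq <- rs$lq
    rh <- vapply(seq_len(d), function(j) rhat(t(hist[, , j])), numeric(1))
    if (!moved && max(rh) < config$rhat_threshold && chunk >= 2) break
  }

  # sampling phase: crossover only
  per_chain <- max(2, ceiling(config$n_retained / nc))
  draws <- array(NA_real_, c(nc, per_chain, d),
                 dimnames = list(NULL, NULL, pars))
  lp <- matrix(NA_real_, nc, per_chain)
  for (r in seq_len(per_chain)) {
    for (s in seq_len(config$thin)) {
      cx <- crossover_step(state, lq, log_q, gamma, config$jitter)
      state <- cx$state; lq <- cx$lq
    }
    draws[, r, ] <- state
    lp[, r] <- lq
  }
  out <- lba_samples(draws, lp, pars, seed = seed %||% NA_integer_,
                     config = config[c("n_retained", "thin",
                                       "migration_prob")])
  out$rhat <- rhat(out)
  out
}

#' Fit a single-participant LBA model by DE-MCMC
#'
#' Thin wrapper gluing [log_posterior_single()] to [run_de_mcmc()], with
#' chains defaulting to three times the number of free parameters and start
#' values drawn from the prior.
#'
#' @param design an [lba_design()] with a prior.
#' @param trials trial data frame.
#' @param config a [de_config()]; \code{n_chains = NULL} means 3x dimension.
#' @param seed optional integer seed.
#' @return an [lba_samples()] object.
#' @export
fit_lba <- function(design, trials, config = de_config(), seed = NULL) {
  log_q <- log_posterior_single(design, trials)
  init <- function(n) sample_prior(design$prior, n)
  run_de_mcmc(log_q, design$pars, init, config, seed)
}
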