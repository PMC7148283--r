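# Marginal-likelihood estimation by warp bridge sampling.
#
# Bridge sampling estimates the evidence from the identity
#   p(y) = E_g[h q] / E_post[h g],
# with g a proposal and h the bridge function minimizing the relative
# mean-square error.  The optimal-bridge estimator is the fixed point of an
# iterative updating scheme over two sets of "heights": l1 over posterior
# draws and l2 over proposal draws.  Warping transforms the posterior draws
# so their first one (Warp-I), two (Warp-II) or three (Warp-III) moments
# match a standard normal proposal; Warp-III symmetrizes by mixing each
# draw with its reflection about the posterior mean, which doubles the
# posterior evaluations but greatly improves overlap for skewed posteriors.

#' Fit proposal moments from posterior draws
#'
#' Sample mean and lower-triangular Cholesky factor of the sample
#' covariance, estimated on the first half of the posterior draws.
#'
#' @param x matrix (draws x parameters) on the real line.
#' @return list with \code{mu} (vector) and \code{R} (lower triangular,
#'   \code{R \%*\% t(R)} = sample covariance).
#' @export
fit_proposal_moments <- function(x) {
  stopifnot(is.matrix(x), nrow(x) > ncol(x))
  mu <- colMeans(x)
  S <- stats::cov(x)
  rank_fail <- function() {
    v <- diag(S)
    worst <- colnames(x)[order(v)[seq_len(min(3, ncol(x)))]] %||%
      order(v)[seq_len(min(3, ncol(x)))]
    stop("posterior covariance is rank deficient; check parameters: ",
         paste(worst, collapse = ", "))
  }
  R <- tryCatch(t(chol(S)), error = function(e) rank_fail())
  dg <- diag(R)
  if (any(dg <= 0) || min(dg) < 1e-7 * max(dg)) rank_fail()
  list(mu = mu, R = R)
}

# log density of the d-dim standard normal at rows of z
log_g_std <- function(z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  -0.5 * ncol(z) * log(2 * pi) - 0.5 * rowSums(z^2)
}

#' Warp heights l1 and l2
#'
#' Computes, on the log scale, the two sets of heights entering the
#' iterative scheme.  At warp level 3,
#' \deqn{l_{1,j} = \frac{|R|}{2}\,[q(2\mu - \theta^*_j) + q(\theta^*_j)]
#'   / g(R^{-1}(\theta^*_j - \mu))}
#' over posterior draws, and analogously l2 over standard-normal proposal
#' draws mapped through mu +/- R theta.  Levels 0/1/2 drop the
#' symmetrization and/or the moment scaling.
#'
#' @param post matrix of posterior draws on the real line (second half).
#' @param prop matrix of standard-normal proposal draws.
#' @param mu,R proposal moments from [fit_proposal_moments()].
#' @param log_q transformed-scale un-normalized log posterior (must include
#'   the Jacobian of any bound transformation); maps matrix rows to a
#'   vector.
#' @param level warp level, 0, 1, 2 or 3.
#' @return list with \code{log_l1} and \code{log_l2} vectors.
#' @export
warp_terms <- function(post, prop, mu, R, log_q, level = 3) {
  stopifnot(level %in% 0:3, is.matrix(post), is.matrix(prop))
  ldetR <- sum(log(diag(R)))
  if (!is.finite(ldetR)) stop("non-finite log determinant of R")
  shift <- function(x, m) sweep(x, 2, m)
  if (level == 0) {
    log_l1 <- eval_logq(log_q, post) - log_g_std(post)
    log_l2 <- eval_logq(log_q, prop) - log_g_std(prop)
  } else if (level == 1) {
    log_l1 <- eval_logq(log_q, post) - log_g_std(shift(post, mu))
    log_l2 <- eval_logq(log_q, shift(prop, -mu)) - log_g_std(prop)
  } else if (level == 2) {
    z <- t(forwardsolve(R, t(shift(post, mu))))
    log_l1 <- ldetR + eval_logq(log_q, post) - log_g_std(z)
    mapped <- shift(prop %*% t(R), -mu)
    log_l2 <- ldetR + eval_logq(log_q, mapped) - log_g_std(prop)
  } else {
    z <- t(forwardsolve(R, t(shift(post, mu))))
    refl <- shift(-post, -2 * mu)               # 2 mu - theta*
    log_l1 <- ldetR - log(2) +
      logaddexp(eval_logq(log_q, refl), eval_logq(log_q, post)) -
      log_g_std(z)
    rt_ <- prop %*% t(R)
    log_l2 <- ldetR - log(2) +
      logaddexp(eval_logq(log_q, shift(-rt_, -mu)),
                eval_logq(log_q, shift(rt_, -mu))) -
      log_g_std(prop)
  }
  list(log_l1 = log_l1, log_l2 = log_l2)
}

#' Iterative updating scheme for the bridge estimator
#'
#' Runs the optimal-bridge fixed-point iteration on the log scale.  All
#' heights are shifted by a common constant (the median of \code{log_l2})
#' for numerical stability and the constant is added back at exit.
#'
#' @param log_l1,log_l2 height vectors from [warp_terms()].
#' @param s1,s2 mixture weights, s1 + s2 = 1; classically N1/(N1+N2) and
#'   N2/(N1+N2), here s1 may be ESS-based.
#' @param tol relative tolerance for convergence.
#' @param max_iter iteration cap.
#' @param init initial guess of the log marginal likelihood.
#' @param on_fail \code{"return"} gives a result with
#'   \code{converged = FALSE}; \code{"error"} raises a condition carrying
#'   the trace.
#' @return list with \code{logml}, \code{iterations}, \code{converged},
#'   and the per-iteration \code{trace} of log estimates.
#' @export
iterate_evidence <- function(log_l1, log_l2, s1 = NULL, s2 = NULL,
                             tol = 1e-10, max_iter = 1000, init = 0,
                             on_fail = c("return", "error")) {
  on_fail <- match.arg(on_fail)
  n1 <- length(log_l1); n2 <- length(log_l2)
  stopifnot(n1 > 0, n2 > 0)
  s1 <- s1 %||% (n1 / (n1 + n2))
  s2 <- s2 %||% (n2 / (n1 + n2))
  stopifnot(abs(s1 + s2 - 1) < 1e-8, tol > 0, max_iter >= 1,
            length(init) == 1, is.finite(init))
  C <- stats::median(log_l2[is.finite(log_l2)])
  a1 <- log_l1 - C
  a2 <- log_l2 - C
  ls1 <- log(s1); ls2 <- log(s2)
  lp <- init - C
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- logmeanexp(a2 - logaddexp(ls1 + a2, ls2 + lp))
    den <- logmeanexp(-logaddexp(ls1 + a1, ls2 + lp))
    lp_new <- num - den
    trace <- c(trace, lp_new + C)
    if (abs(expm1(lp_new - lp)) <= tol) {
      lp <- lp_new
      converged <- TRUE
      break
    }
    lp <- lp_new
  }
  out <- list(logml = lp + C, iterations = length(trace),
              converged = converged, trace = trace)
  if (!converged && on_fail == "error") {
    cond <- structure(class = c("bridge_nonconvergence", "error",
                                "condition"),
                      list(message = "bridge iteration did not converge",
                           call = sys.call(), trace = trace))
    stop(cond)
  }
  out
}

#' Detect a period-2 oscillation in an iteration trace
#'
#' When the updating scheme stalls by alternating between two values, the
#' recommended remedy is a restart from their geometric mean.  On the log
#' scale that is the arithmetic mean of the two cluster values.
#'
#' @param trace numeric vector of log estimates.
#' @param tol relative tolerance separating "same cluster" from "distinct".
#' @return restart value (log scale) or NULL when no oscillation is found.
#' @export
detect_oscillation <- function(trace, tol = 1e-10) {
  m <- length(trace)
  if (m < 6) return(NULL)
  tail_ <- trace[(m - 5):m]
  odd <- tail_[c(1, 3, 5)]
  even <- tail_[c(2, 4, 6)]
  within <- function(v) max(abs(v - mean(v))) <= max(1e-8, 100 * tol *
                                                       max(1, abs(mean(v))))
  gap <- abs(mean(odd) - mean(even))
  if (within(odd) && within(even) &&
      gap > tol * max(1, abs(mean(tail_))) * 10)
    return(mean(c(mean(odd), mean(even))))
  NULL
}

#' Marginal-likelihood result container
#' @keywords internal
marglik_result <- function(logml, iterations, converged, restarted, level,
                           n1, n2, ess) {
  structure(list(logml = logml, iterations = iterations,
                 converged = converged, restarted = restarted,
                 warp_level = level, n1 = n1, n2 = n2, ess = ess),
            class = "lba_marglik")
}

#' @export
print.lba_marglik <- function(x, ...) {
  cat(sprintf("log marginal likelihood: %.4f (Warp-%s)\n", x$logml,
              c("0", "I", "II", "III")[x$warp_level + 1]))
  cat(sprintf("  iterations %d, converged %s%s, N1 = %d, N2 = %d, ESS = %.0f\n",
              x$iterations, x$converged,
              if (x$restarted) " (after restart)" else "", x$n1, x$n2,
              x$ess))
  invisible(x)
}

#' Warp bridge-sampling estimate of the marginal likelihood
#'
#' Orchestrates the full estimator: pool chains, transform bounded
#' parameters to the real line with their Jacobians, split the retained
#' iterations of each chain in half, fit the proposal moments on the first
#' half, draw standard-normal proposals, compute the warp heights on the
#' second half, and run the iterative scheme with ESS-based weights.  A
#' period-2 oscillation of the scheme triggers one restart from the
#' geometric mean of the two values.
#'
#' @param samples an [lba_samples()] object (a warning is issued if any
#'   split R-hat exceeds 1.1).
#' @param log_q natural-scale un-normalized log posterior mapping matrix
#'   rows to a vector.
#' @param bounds list with \code{lower}/\code{upper} vectors per parameter.
#' @param level warp level 0-3; 3 symmetrizes and is the default.
#' @param n_proposal number of proposal draws N2; defaults to the size of
#'   the second half.
#' @param tol,max_iter,init iterative-scheme controls (see
#'   [iterate_evidence()]).
#' @param use_ess use the minimum-across-parameters effective sample size
#'   of the second half in the bridge weights (s1), rather than the raw
#'   draw count.
#' @return an \code{"lba_marglik"} result.
#' @export
warp_marglik <- function(samples, log_q, bounds, level = 3,
                         n_proposal = NULL, tol = 1e-10, max_iter = 1000,
                         init = 0, use_ess = TRUE) {
  stopifnot(inherits(samples, "lba_samples"))
  if (!is.null(samples$rhat) && any(samples$rhat > 1.1, na.rm = TRUE))
    warning("some split R-hat exceed 1.1; bridge estimate may be unreliable")
  halves <- split_halves(samples)
  d <- length(samples$pars)

  t1 <- transform_samples(halves$first, bounds)
  t2 <- transform_samples(halves$second, bounds)
  log_q_omega <- function(omega) {
    if (!is.matrix(omega)) omega <- matrix(omega, nrow = 1)
    theta <- untransform_samples(omega, bounds)
    colnames(theta) <- samples$pars
    eval_logq(log_q, theta) + log_jacobian_rows(omega, bounds)
  }

  mom <- fit_proposal_moments(t1$omega)
  n1 <- nrow(t2$omega)
  n2 <- n_proposal %||% n1
  prop <- matrix(rnorm(n2 * d), n2, d)

  terms <- warp_terms(t2$omega, prop, mom$mu, mom$R, log_q_omega, level)

  ess_half2 <- if (use_ess) {
    sec <- halves$second_array
    min(vapply(seq_len(d), function(j) ess(t(sec[, , j])), numeric(1)))
  } else n1
  s1 <- ess_half2 / (ess_half2 + n2)
  s2 <- n2 / (ess_half2 + n2)

  fit <- iterate_evidence(terms$log_l1, terms$log_l2, s1, s2, tol = tol,
                          max_iter = max_iter, init = init)
  restarted <- FALSE
  if (!fit$converged) {
    new_init <- detect_oscillation(fit$trace, tol)
    if (!is.null(new_init)) {
      fit <- iterate_evidence(terms$log_l1, terms$log_l2, s1, s2,
                              tol = tol, max_iter = max_iter,
                              init = new_init, on_fail = "error")
      restarted <- TRUE
    } else {
      cond <- structure(class = c("bridge_nonconvergence", "error",
                                  "condition"),
                        list(message = "bridge iteration did not converge and no oscillation was detected",
                             call = sys.call(), trace = fit$trace))
      stop(cond)
    }
  }
  marglik_result(fit$logml, fit$iterations, fit$converged, restarted,
                 level, n1, n2, ess_half2)
}

#' Simple Monte Carlo estimate of the marginal likelihood
#'
#' Averages likelihood values over prior draws (on the log scale).
#' Inefficient when the posterior concentrates relative to the prior, but a
#' useful baseline and cross-check.
#'
#' @param loglik function mapping a matrix of parameter rows to a vector of
#'   log likelihood values.
#' @param prior an [prior_spec()] table (proper).
#' @param n number of prior draws.
#' @return an \code{"lba_marglik"} result (warp level NA).
#' @export
simple_mc_marglik <- function(loglik, prior, n = 1e5) {
  draws <- sample_prior(prior, n)
  ll <- eval_logq(loglik, draws)
  marglik_result(logmeanexp(ll), 0L, TRUE, FALSE, NA_integer_, 0L, n, n)
}

#' Savage-Dickey density ratio for a nested comparison
#'
#' log BF in favor of the restricted model (BF01) as the log ratio of the
#' posterior to the prior density of the constrained component at the test
#' value.  The posterior density is estimated with a Gaussian kernel and
#' Sheather-Jones plug-in bandwidth (falling back to Silverman's rule when
#' that fails).
#'
#' @param draws posterior draws of the test component (on a scale where the
#'   kernel estimate is sensible, typically unbounded).
#' @param log_prior_at log prior density at the test value.
#' @param test_value the constrained value.
#' @return log BF01 (restricted over full).
#' @export
savage_dickey_logbf <- function(draws, log_prior_at, test_value) {
  stopifnot(length(draws) > 10)
  qs <- stats::quantile(draws, c(0.005, 0.995))
  if (test_value < qs[1] || test_value > qs[2])
    warning("test value lies outside the central 99% of the posterior draws; Savage-Dickey estimate may be unstable")
  bw <- tryCatch(stats::bw.SJ(draws), error = function(e) stats::bw.nrd0(draws))
  dens <- stats::density(draws, bw = bw, n = 1024,
                         from = min(draws, test_value) - 3 * bw,
                         to = max(draws, test_value) + 3 * bw)
  post_at <- stats::approx(dens$x, dens$y, xout = test_value)$y
  if (!is.finite(post_at) || post_at <= 0)
    stop("no posterior density mass near the test value; estimate unstable")
  log(post_at) - log_prior_at
}

#' Bayes factor from two marginal likelihoods
#'
#' @param ml1,ml2 \code{"lba_marglik"} results (or bare log values).
#' @return list of class \code{"lba_bf"} with \code{log_bf}, \code{bf}, and
#'   the two component results.
#' @export
bayes_factor <- function(ml1, ml2) {
  l1 <- if (inherits(ml1, "lba_marglik")) ml1$logml else ml1
  l2 <- if (inherits(ml2, "lba_marglik")) ml2$logml else ml2
  structure(list(log_bf = l1 - l2, bf = exp(l1 - l2),
                 ml1 = ml1, ml2 = ml2),
            class = "lba_bf")
}

#' @export
print.lba_bf <- function(x, ...) {
  cat(sprintf("log BF = %.4f (BF = %.4g)\n", x$log_bf, x$bf))
  invisible(x)
}

#' Repeat an estimator and summarize its spread
#'
#' Runs an estimation closure under independently derived seeds and reports
#' the median and min-max range: the recommended, assumption-free way to
#' quantify the uncertainty of simulation-based evidence estimates.
#'
#' @param fn function(seed) returning a scalar estimate (e.g. a log Bayes
#'   factor) for one independent repetition.
#' @param repetitions number of repetitions (>= 1).
#' @param seed master seed from which per-repetition seeds are derived.
#' @return list with \code{estimates}, \code{median}, \code{range}.
#' @export
repeat_estimates <- function(fn, repetitions = 10, seed = 1) {
  stopifnot(repetitions >= 1)
  seeds <- seed + seq_len(repetitions) * 1009L
  est <- numeric(repetitions)
  fails <- character(0)
  for (r in seq_len(repetitions)) {
    est[r] <- tryCatch(fn(seeds[r]), error = function(e) {
      fails <<- c(fails, sprintf("repetition %d: %s", r, conditionMessage(e)))
      NA_real_
    })
  }
  if (length(fails))
    stop("repetitions failed:\n", paste(fails, collapse = "\n"))
  list(estimates = est, median = stats::median(est), range = range(est))
}
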