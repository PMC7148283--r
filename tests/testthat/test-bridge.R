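# Bridge estimator components and alternative estimators.

test_that("proposal moments are the sample mean and Cholesky factor", {
  # hand Cholesky of [[4,2],[2,3]]
  set.seed(51)
  z <- matrix(rnorm(2e5), ncol = 2)
  S <- matrix(c(4, 2, 2, 3), 2)
  x <- sweep(z, 2, colMeans(z))                 # exact zero mean
  x <- x %*% solve(chol(cov(x))) %*% chol(S)    # exact covariance S
  mom <- fit_proposal_moments(x)
  expect_equal(mom$mu, c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(mom$R), rbind(c(2, 0), c(1, sqrt(2))),
               tolerance = 1e-10)
  # 1-D: R is the sample SD
  y <- matrix(rnorm(500, 3, 2))
  expect_equal(as.numeric(fit_proposal_moments(y)$R), sd(y))
  # exact collinearity is reported
  bad <- cbind(a = z[1:100, 1], b = 2 * z[1:100, 1])
  expect_error(fit_proposal_moments(bad), "rank deficient")
})

test_that("warp heights are exactly one when target and proposal coincide", {
  set.seed(52)
  d <- 3
  post <- matrix(rnorm(300 * d), ncol = d)
  prop <- matrix(rnorm(200 * d), ncol = d)
  log_q <- function(x) -0.5 * d * log(2 * pi) - 0.5 * rowSums(x^2)
  for (lev in 0:3) {
    w <- warp_terms(post, prop, mu = rep(0, d), R = diag(d), log_q, lev)
    expect_equal(w$log_l1, rep(0, nrow(post)), tolerance = 1e-12)
    expect_equal(w$log_l2, rep(0, nrow(prop)), tolerance = 1e-12)
  }
})

test_that("level-III heights match a directly coded expression and are symmetric", {
  # 1-D skewed target: unnormalized gamma density on the log scale
  g <- gamma_fixture(a = 2.5, b = 1.5)
  log_q <- function(x) g$log_q(x)   # on the positive scale, draws kept > 0
  post <- matrix(c(0.4, 1.3, 2.9), ncol = 1)
  prop <- matrix(c(-0.7, 0.2), ncol = 1)
  mu <- 1.1; R <- matrix(0.8)
  w <- warp_terms(post, prop, mu, R, log_q, level = 3)
  for (j in 1:3) {
    th <- post[j, 1]
    direct <- log(0.8 / 2 * (exp(g$log_q(matrix(2 * mu - th))) +
                               exp(g$log_q(matrix(th)))) /
                    dnorm((th - mu) / 0.8))
    expect_equal(w$log_l1[j], direct, tolerance = 1e-12)
  }
  refl <- matrix(2 * mu - post, ncol = 1)
  w2 <- warp_terms(refl, prop, mu, R, log_q, level = 3)
  expect_equal(w$log_l1, w2$log_l1, tolerance = 1e-12)
})

test_that("the updating scheme hits fixed points, matches a root finder, and ignores the start", {
  # constant heights: fixed point is the constant, reached in <= 2 steps
  r <- iterate_evidence(rep(log(7), 50), rep(log(7), 40))
  expect_equal(r$logml, log(7), tolerance = 1e-12)
  expect_lte(r$iterations, 2)
  expect_true(r$converged)

  set.seed(53)
  l1 <- rnorm(200, 2, 1); l2 <- rnorm(150, 1.5, 1)
  ra <- iterate_evidence(l1, l2, init = 0)
  rb <- iterate_evidence(l1, l2, init = 40)
  expect_lt(abs(ra$logml - rb$logml), 1e-8 * max(1, abs(ra$logml)))
  # independent bracketing root finder on the bridge identity
  s1 <- 200 / 350; s2 <- 150 / 350
  fp <- function(lp) {
    num <- log(mean(exp(l2) / (s1 * exp(l2) + s2 * exp(lp))))
    den <- log(mean(1 / (s1 * exp(l1) + s2 * exp(lp))))
    num - den - lp
  }
  root <- uniroot(fp, c(-20, 20), tol = 1e-14)$root
  expect_lt(abs(ra$logml - root), 1e-8 * max(1, abs(root)))
})

test_that("period-2 oscillations are detected and the geometric-mean restart converges", {
  # exact alternation between log 2 and log 8 restarts at log 4
  tr <- rep(c(log(2), log(8)), 5)
  expect_equal(detect_oscillation(tr), log(4))
  expect_null(detect_oscillation(log(seq(2, 3, length.out = 10))))
  expect_null(detect_oscillation(c(1, 2)))

  # adversarial heights that genuinely stall the scheme
  set.seed(31)
  l1 <- rnorm(5, 500, 1); l2 <- rnorm(5, -500, 50)
  s1 <- 0.953695; s2 <- 1 - s1
  r <- iterate_evidence(l1, l2, s1, s2, tol = 1e-12, max_iter = 60,
                        init = 89.755437)
  expect_false(r$converged)
  restart <- detect_oscillation(r$trace, 1e-12)
  expect_false(is.null(restart))
  r2 <- iterate_evidence(l1, l2, s1, s2, tol = 1e-12, max_iter = 500,
                         init = restart)
  expect_true(r2$converged)
  expect_error(iterate_evidence(l1, l2, s1, s2, tol = 1e-12, max_iter = 60,
                                init = 89.755437, on_fail = "error"),
               class = "bridge_nonconvergence")
})

test_that("warp bridge reproduces a conjugate closed form at all warp levels", {
  fx <- conjugate_fixture(n_draws = 6000, seed = 54)
  for (lev in c(0, 2, 3)) {
    set.seed(lev + 1)
    r <- warp_marglik(fx$samples, fx$log_q, fx$bounds, level = lev)
    expect_true(r$converged)
    expect_equal(r$logml, fx$logml, tolerance = 0.02)
  }
})

test_that("simple Monte Carlo averages the likelihood over the prior", {
  # constant likelihood: estimate is exact for any draw count
  prior <- prior_spec("x", 0, 1)
  r <- simple_mc_marglik(function(m) rep(log(0.3), nrow(m)), prior, n = 37)
  expect_equal(r$logml, log(0.3), tolerance = 1e-12)

  fx <- conjugate_fixture(seed = 55)
  set.seed(56)
  loglik <- function(m) vapply(m[, 1], function(t)
    sum(dnorm(fx$y, t, fx$sigma, log = TRUE)), numeric(1))
  pr <- prior_spec("theta", fx$mu0, fx$tau0)
  r2 <- simple_mc_marglik(loglik, pr, n = 1e5)
  # bootstrap standard error of the log-mean-exp
  set.seed(57)
  draws <- sample_prior(pr, 1e5)
  ll <- loglik(draws)
  boots <- replicate(200, {
    i <- sample.int(length(ll), replace = TRUE)
    m <- max(ll[i]); m + log(mean(exp(ll[i] - m)))
  })
  expect_lt(abs(r2$logml - fx$logml), 3 * sd(boots))
})

test_that("warp bridge and simple Monte Carlo agree on a toy model", {
  fx <- conjugate_fixture(n_obs = 10, n_draws = 6000, seed = 58, tau0 = 1)
  set.seed(59)
  w <- warp_marglik(fx$samples, fx$log_q, fx$bounds, level = 3)
  loglik <- function(m) vapply(m[, 1], function(t)
    sum(dnorm(fx$y, t, fx$sigma, log = TRUE)), numeric(1))
  m <- simple_mc_marglik(loglik, prior_spec("theta", fx$mu0, fx$tau0),
                         n = 2e5)
  expect_lt(abs(w$logml - m$logml), 0.05)
})

test_that("Savage-Dickey ratio matches the conjugate closed form and flags tail tests", {
  fx <- conjugate_fixture(seed = 60)
  set.seed(61)
  draws <- rnorm(1e5, fx$post_mean, sqrt(fx$post_var))
  test_value <- fx$post_mean + 0.5 * sqrt(fx$post_var)
  lbf <- savage_dickey_logbf(draws, dnorm(test_value, fx$mu0, fx$tau0,
                                          log = TRUE), test_value)
  exact <- dnorm(test_value, fx$post_mean, sqrt(fx$post_var), log = TRUE) -
    dnorm(test_value, fx$mu0, fx$tau0, log = TRUE)
  expect_lt(abs(lbf - exact), log(1.05))
  # no updating: posterior equals prior gives BF01 of one
  set.seed(62)
  prior_draws <- rnorm(2e4, 0, 1)
  lbf0 <- savage_dickey_logbf(prior_draws, dnorm(0.3, log = TRUE), 0.3)
  expect_lt(abs(lbf0), log(1.1))
  expect_warning(savage_dickey_logbf(prior_draws, dnorm(4, log = TRUE), 4),
                 "central 99%")
})

test_that("Bayes factors compose antisymmetrically from marginal likelihoods", {
  expect_equal(bayes_factor(-10, -10)$bf, 1)
  expect_equal(bayes_factor(-10 + log(10), -10)$bf, 10)
  ab <- bayes_factor(-3.2, -7.9)
  ba <- bayes_factor(-7.9, -3.2)
  expect_equal(ab$bf * ba$bf, 1, tolerance = 1e-12)
})

test_that("repeated estimation reports median and range over seeded runs", {
  one <- repeat_estimates(function(seed) 4.2, repetitions = 1)
  expect_equal(one$median, 4.2)
  expect_equal(diff(one$range), 0)
  det <- repeat_estimates(function(seed) 1.5, repetitions = 5)
  expect_equal(diff(det$range), 0)
  fx <- conjugate_fixture(seed = 63)
  est <- function(n_draws) function(seed) {
    set.seed(seed)
    draws <- array(rnorm(3 * ceiling(n_draws / 3), fx$post_mean,
                         sqrt(fx$post_var)), c(3, ceiling(n_draws / 3), 1))
    warp_marglik(lba_samples(draws), fx$log_q, fx$bounds)$logml
  }
  small <- repeat_estimates(est(600), repetitions = 6, seed = 2)
  big <- repeat_estimates(est(6000), repetitions = 6, seed = 2)
  expect_lt(diff(big$range), diff(small$range) + 1e-4)
})
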