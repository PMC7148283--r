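# Single-accumulator distributions, defective race density, likelihood and
# simulator.

acc <- list(A = 0.5, b = 1.5, v = 4, s = 1)
race2 <- race_params(0.2, list(
  r1 = list(A = 0.5, b = 1.5, v = 4, s = 1),
  r2 = list(A = 0.5, b = 1.5, v = 3, s = 1)))

test_that("finishing-time CDF has correct limits and matches simulation", {
  expect_equal(lba_cdf(0, acc$A, acc$b, acc$v, acc$s), 0)
  expect_equal(lba_cdf(1e6, acc$A, acc$b, acc$v, acc$s), 1, tolerance = 1e-8)
  # monotone in t
  tt <- seq(0.01, 3, length.out = 200)
  Fv <- lba_cdf(tt, acc$A, acc$b, acc$v, acc$s)
  expect_true(all(diff(Fv) >= 0))
  # empirical CDF oracle at t = 0.3: simulate finishing times directly from
  # the generative story (uniform start, zero-truncated normal rate)
  set.seed(11)
  n <- 1e6
  ft <- (acc$b - runif(n, 0, acc$A)) / rtnorm(n, acc$v, acc$s, lower = 0)
  p_hat <- mean(ft <= 0.3)
  p <- lba_cdf(0.3, acc$A, acc$b, acc$v, acc$s)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p - p_hat), 3 * se)
})

test_that("finishing-time density integrates to one and differentiates the CDF", {
  expect_equal(lba_pdf(0, acc$A, acc$b, acc$v, acc$s), 0)
  total <- integrate(lba_pdf, 0, Inf, A = acc$A, b = acc$b, v = acc$v,
                     s = acc$s, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  h <- 1e-6
  fd <- (lba_cdf(0.3 + h, acc$A, acc$b, acc$v, acc$s) -
           lba_cdf(0.3 - h, acc$A, acc$b, acc$v, acc$s)) / (2 * h)
  expect_equal(lba_pdf(0.3, acc$A, acc$b, acc$v, acc$s), fd,
               tolerance = 1e-5)
  expect_true(all(lba_pdf(seq(0.01, 5, by = 0.01), acc$A, acc$b, acc$v,
                          acc$s) >= 0))
})

test_that("degenerate start-point range uses the single-point form", {
  # A = 0: finishing time is b / rate with a zero-truncated normal rate
  p_exact <- pnorm((4 - 1.5 / 0.4) / 1) / pnorm(4)
  expect_equal(lba_cdf(0.4, 0, 1.5, 4, 1), p_exact, tolerance = 1e-12)
  total <- integrate(lba_pdf, 0, Inf, A = 0, b = 1.5, v = 4, s = 1)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("parameter validation rejects impossible accumulators", {
  expect_error(lba_cdf(0.3, A = 0.5, b = 0.4, v = 4, s = 1), "b >= A")
  expect_error(lba_pdf(0.3, A = 0.5, b = 1.5, v = 4, s = -1), "s > 0")
})

test_that("defective density is a structural zero below t0 and conserves mass", {
  expect_identical(dlba_race(0.19, "r1", race2), -Inf)
  expect_error(dlba_race(0.5, "r9", race2), "unknown response")
  total <- integrate(function(t) exp(dlba_race(t, "r1", race2)), 0.2, Inf,
                     rel.tol = 1e-9)$value +
    integrate(function(t) exp(dlba_race(t, "r2", race2)), 0.2, Inf,
              rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("defective density matches an empirical joint-probability oracle", {
  # P(response = r1, RT <= 0.5) by quadrature of the defective density vs
  # direct simulation of the race
  set.seed(12)
  n <- 1e5
  trials <- simulate_race(race2, n)
  p_hat <- mean(trials$response == "r1" & trials$rt <= 0.5)
  p <- integrate(function(t) exp(dlba_race(t, "r1", race2)), 0.2, 0.5,
                 rel.tol = 1e-9)$value
  expect_lt(abs(p - p_hat), 3 * sqrt(p * (1 - p) / n))
})

test_that("log likelihood sums defective log densities over trials", {
  resolver <- function(cond, stim) race2
  empty <- data.frame(subject = character(), condition = character(),
                      stimulus = character(), response = character(),
                      rt = numeric())
  expect_identical(lba_loglik(empty, resolver), 0)
  one <- data.frame(subject = "s1", condition = "1", stimulus = "s1",
                    response = "r1", rt = 0.5)
  expect_equal(lba_loglik(one, resolver), dlba_race(0.5, "r1", race2))
  # the generating parameters beat a badly distorted drift rate
  set.seed(13)
  full <- single_design("full")
  theta <- study1_generating_values()
  trials <- simulate_design(full, theta, 250)
  bad <- theta; bad["v_true"] <- 0.5
  expect_gt(design_loglik(full, theta, trials),
            design_loglik(full, bad, trials))
})

test_that("simulator respects non-decision time and degenerate start range", {
  set.seed(14)
  tr <- simulate_race(race2, 2000)
  expect_true(all(tr$rt > race2$t0))
  expect_identical(nrow(simulate_race(race2, 0)), 0L)
  # A = 0 with near-deterministic rates: RT pinned at t0 + b / v
  det <- race_params(0.2, list(
    r1 = list(A = 0, b = 1.5, v = 4, s = 1e-9),
    r2 = list(A = 0, b = 1.5, v = 2, s = 1e-9)))
  trd <- simulate_race(det, 200)
  expect_true(all(abs(trd$rt - (0.2 + 1.5 / 4)) < 1e-6))
  expect_true(all(trd$response == "r1"))
})

test_that("simulated response frequencies match quadrature of the defective densities", {
  set.seed(15)
  n <- 2e4
  tr <- simulate_race(race2, n)
  p1 <- integrate(function(t) exp(dlba_race(t, "r1", race2)), 0.2, Inf)$value
  expect_lt(abs(mean(tr$response == "r1") - p1),
            3 * sqrt(p1 * (1 - p1) / n))
})
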