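# Design resolution, priors, single-participant posterior, configuration IO.

test_that("null, V and B designs resolve cells as specified", {
  theta0 <- c(A = 1, B = 0.4, v_true = 3, v_false = 1, s_false = 1, t0 = 0.3)
  null <- hier_design("0")$design
  r1 <- resolve_design(null, theta0, "1", "s1")
  r2 <- resolve_design(null, theta0, "2", "s1")
  expect_equal(r1, r2)

  thetav <- c(A = 1, B = 0.4, v_true.1 = 4, v_true.2 = 3, v_false = 1,
              s_false = 1, t0 = 0.3)
  vmod <- hier_design("V")$design
  expect_equal(resolve_design(vmod, thetav, "1", "s1")$accumulators$r1$v, 4)
  expect_equal(resolve_design(vmod, thetav, "2", "s1")$accumulators$r1$v, 3)
  # mismatching accumulator gets v_false in both conditions
  expect_equal(resolve_design(vmod, thetav, "1", "s1")$accumulators$r2$v, 1)

  thetab <- c(A = 1, B.1 = 0.3, B.2 = 0.7, v_true = 3.5, v_false = 1,
              s_false = 1, t0 = 0.3)
  bmod <- hier_design("B")$design
  b1 <- resolve_design(bmod, thetab, "1", "s1")$accumulators$r1$b
  b2 <- resolve_design(bmod, thetab, "2", "s1")$accumulators$r1$b
  expect_equal(b2 - b1, 0.7 - 0.3)
  expect_error(resolve_design(bmod, thetab, "3", "s1"), "unknown condition")
})

test_that("swapping stimulus and response labels together leaves the likelihood invariant", {
  set.seed(21)
  full <- single_design("full")
  theta <- study1_generating_values()
  trials <- simulate_design(full, theta, 60)
  swapped <- trials
  swapped$stimulus <- c(s1 = "s2", s2 = "s1")[trials$stimulus]
  swapped$response <- c(r1 = "r2", r2 = "r1")[trials$response]
  expect_equal(design_loglik(full, theta, swapped),
               design_loglik(full, theta, trials))
})

test_that("priors are truncated, normalized and match an independent density", {
  prior <- default_prior_single()
  theta <- c(A = 1, B = 1, v_true = 2, v_false = 1, t0 = 0.05)
  expect_identical(log_prior(theta, prior), -Inf)  # t0 below 0.1
  # marginal normalization by quadrature
  for (i in seq_len(nrow(prior)))
    expect_equal(integrate(dtnorm, max(prior$lower[i], -50), 50,
                           mean = prior$mean[i], sd = prior$sd[i],
                           lower = prior$lower[i],
                           upper = prior$upper[i])$value,
                 1, tolerance = 1e-6)
  # A = 1 under its zero-bounded prior vs independently coded density
  pa <- prior_spec("A", 1, 1, 0, Inf)
  expect_equal(log_prior(c(A = 1), pa),
               dnorm(1, 1, 1, log = TRUE) - log(1 - pnorm(0, 1, 1)),
               tolerance = 1e-12)
})

test_that("prior sampling honors truncation, moments and seeding", {
  prior <- default_prior_single()
  set.seed(22)
  x <- sample_prior(prior, 1e5)
  expect_true(all(x[, "t0"] > 0.1))
  expect_true(all(x[, "A"] > 0))
  m <- tnorm_mean(1, 1, 0)
  sdm <- sd(x[, "A"]) / sqrt(nrow(x))
  expect_lt(abs(mean(x[, "A"]) - m), 3 * sdm)
  set.seed(99); d1 <- sample_prior(prior, 10)
  set.seed(99); d2 <- sample_prior(prior, 10)
  expect_identical(d1, d2)
  expect_error(sample_prior(prior_spec("x", Inf, 1), 2), "improper")
})

test_that("single-participant posterior adds likelihood and prior on the natural scale", {
  set.seed(23)
  full <- single_design("full")
  theta <- study1_generating_values()
  trials <- simulate_design(full, theta, 100)
  lp <- log_posterior_single(full, trials)
  expect_equal(lp(theta),
               design_loglik(full, theta, trials) +
                 log_prior(theta, full$prior))
  out <- theta; out["A"] <- -0.2
  expect_identical(lp(out), -Inf)
  jittered <- theta; jittered["t0"] <- 0.11
  expect_gt(lp(theta), lp(jittered))
})

test_that("restricted design fixes the matching drift rate as a constant", {
  res <- single_design("restricted")
  expect_false("v_true" %in% res$pars)
  expect_equal(unname(res$constants["v_true"]), 3.55)
  expect_false("v_true" %in% res$prior$par)
  race <- resolve_design(res, c(A = 0.5, B = 1, v_false = 3, t0 = 0.2),
                         "1", "s1")
  expect_equal(race$accumulators$r1$v, 3.55)
})

test_that("model configuration files round-trip through YAML and JSON", {
  d <- single_design("restricted", v_true_fixed = 3.4)
  d$prior$mean[d$prior$par == "A"] <- 2
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(d, path)
    d2 <- read_model_config(path)
    expect_equal(d2$constants[["v_true"]], 3.4)
    expect_equal(d2$prior, d$prior)
  }
  h <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(hier_design("B_res"), h)
  expect_s3_class(read_model_config(h), "lba_hier")
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(type = "single", model = "full",
                        prior = list(list(par = "zzz", mean = 0, sd = 1))),
                   bad)
  expect_error(read_model_config(bad), "unknown parameter")
})
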