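test_that("the psychometric function has the cumulative-Gaussian form", {
  expect_equal(detection_probability(5, 5, 1), 0.5)
  expect_equal(detection_probability(6, 5, 1), pnorm(-1))
  expect_equal(detection_probability(0.01, 8, 0.5), 1, tolerance = 1e-9)
  steps <- seq(0.5, 12, by = 0.5)
  expect_true(all(diff(detection_probability(steps, 5, 2)) < 0))
  expect_error(detection_probability(1, 5, 0), "width")
  expect_error(detection_probability(1, 5, -2), "width")
})

test_that("maximum likelihood recovers the generating parameters", {
  dmax <- 5; sigma <- 1
  steps <- seq(2, 8, by = 0.75)
  p <- detection_probability(steps, dmax, sigma)
  set.seed(41)
  n_det <- rbinom(length(steps), 1e4, p)
  fit <- fit_psychometric(steps, n_det, rep(1e4, length(steps)))
  expect_equal(fit$dmax_deg, dmax, tolerance = 0.02)
  expect_equal(fit$width_deg, sigma, tolerance = 0.02)
  # the fitted curve passes through 50% at the fitted Dmax, exactly
  expect_equal(detection_probability(fit$dmax_deg, fit$dmax_deg,
                                     fit$width_deg), 0.5)
  # local optimality of the likelihood
  base <- logLik_at <- function(d, s) {
    pp <- pmin(pmax(detection_probability(steps, d, s), 1e-9), 1 - 1e-9)
    sum(dbinom(n_det, 1e4, pp, log = TRUE))
  }
  ll_hat <- logLik_at(fit$dmax_deg, fit$width_deg)
  for (f in c(0.9, 1.1)) {
    expect_gte(ll_hat, logLik_at(fit$dmax_deg * f, fit$width_deg))
    expect_gte(ll_hat, logLik_at(fit$dmax_deg, fit$width_deg * f))
  }
})

test_that("step-function data give a midpoint threshold", {
  steps <- c(1, 2, 3, 4, 5)
  n_det <- c(20, 20, 20, 0, 0)
  fit <- fit_psychometric(steps, n_det, rep(20, 5))
  expect_gt(fit$dmax_deg, 3)
  expect_lt(fit$dmax_deg, 4)
  expect_lt(fit$width_deg, 0.5)
})

test_that("degenerate detection data are rejected with guidance", {
  expect_error(fit_psychometric(c(1, 2), c(10, 10), c(10, 10)),
               "non-identifiable")
  expect_error(fit_psychometric(c(1, 2), c(0, 0), c(10, 10)),
               "non-identifiable")
  expect_error(fit_psychometric(c(1, 1), c(3, 4), c(10, 10)), "distinct")
})

test_that("bootstrap intervals cover the point estimate", {
  steps <- seq(2, 8, by = 1.5)
  p <- detection_probability(steps, 5, 1.2)
  set.seed(7)
  n_det <- rbinom(length(steps), 60, p)
  fit <- fit_psychometric(steps, n_det, rep(60, length(steps)), n_boot = 60,
                          seed = 2)
  expect_lt(fit$ci$dmax_deg[[1]], fit$dmax_deg)
  expect_gt(fit$ci$dmax_deg[[2]], fit$dmax_deg)
})

test_that("power-law fitting is exact on noiseless data and flags saturation", {
  x <- c(0.5, 1, 2, 4, 8)
  y <- 5.36 * x^0.462
  fit <- fit_power_law(x, y)
  expect_equal(fit$k, 5.36, tolerance = 1e-4)
  expect_equal(fit$exponent, 0.462, tolerance = 1e-4)
  expect_equal(fit$S, 0, tolerance = 1e-4)
  two <- fit_power_law(c(1, 4), c(3, 7))
  expect_true(two$underdetermined)
  expect_equal(two$S, 0)
  expect_equal(predict(two, c(1, 4)), c(3, 7), tolerance = 1e-6)
  expect_error(fit_power_law(c(-1, 2), c(1, 2)), "domain")
})

test_that("fixing the exponent reduces to the closed-form coefficient", {
  x <- c(1, 2, 5)
  y <- c(4, 7, 12)
  e <- 0.462
  fit <- fit_power_law(x, y, fixed_exponent = e)
  expect_equal(fit$k, sum(y * x^e) / sum(x^(2 * e)), tolerance = 1e-12)
  expect_equal(fit$exponent, e)
  # S uses n - 1 degrees of freedom when only k is free
  res <- y - fit$k * x^e
  expect_equal(fit$S, sqrt(sum(res^2) / 2), tolerance = 1e-12)
})

test_that("power-law fits are scale-covariant", {
  x <- c(0.5, 1, 3, 6)
  set.seed(3)
  y <- 4 * x^0.5 + rnorm(4, sd = 0.1)
  base <- fit_power_law(x, y)
  cx <- fit_power_law(2 * x, y)
  expect_equal(cx$exponent, base$exponent, tolerance = 1e-4)
  expect_equal(cx$k, base$k * 2^(-base$exponent), tolerance = 1e-4)
  cy <- fit_power_law(x, 3 * y)
  expect_equal(cy$k, 3 * base$k, tolerance = 1e-4)
  expect_equal(cy$S, 3 * base$S, tolerance = 1e-4)
})

test_that("the exponent is recovered on average from noisy points", {
  x <- c(0.5, 1, 2, 4, 6, 9.55)
  truth_e <- 0.462
  exps <- vapply(1:500, function(r) {
    rng <- apparentmotion:::local_rng(1000 + r)
    y <- 5.36 * x^truth_e + rng$rnorm(6, sd = 0.3)
    fit_power_law(x, y)$exponent
  }, numeric(1))
  expect_lt(abs(mean(exps) - truth_e), 0.05)
})

test_that("optics conversions reproduce the published acceptance angles", {
  expect_equal(acceptance_angle(1.07), 2.5145)
  expect_equal(round(acceptance_angle(1.07), 1), 2.5)
  expect_equal(round(acceptance_angle(3.42)), 8)
  expect_equal(interommatidial_angle(2.5), 2.5)
  expect_error(acceptance_angle(0), "domain")
  expect_error(interommatidial_angle(-1), "domain")
})

test_that("per-element fits show Dmax increasing with element size", {
  elements <- c(0.5, 2, 8)
  trials <- synth_behavior(elements, lapply(elements, function(el) {
    transition_steps(5.36 * el^0.462, n_steps = 6)
  }), 120, seed = 12)
  fits <- fit_psychometric_by_element(trials)
  expect_equal(fits$element_size_deg, elements)
  expect_true(all(diff(fits$dmax_deg) > 0))
})
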