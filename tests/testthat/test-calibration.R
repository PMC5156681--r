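test_that("fit_dark_prior returns sample moments", {
  two <- fit_dark_prior(c(-1, 1))
  expect_equal(two$mean, 0)
  expect_equal(sqrt(two$var), sqrt(2))
  expect_warning(flat <- fit_dark_prior(c(0, 0, 0, 0)), "degenerate")
  expect_equal(flat$mean, 0)
  expect_true(isTRUE(attr(flat, "degenerate_sd")))
  expect_error(fit_dark_prior(1), "at least 2")

  set.seed(31)
  x <- rnorm(1e4, -0.622, 2.08)
  fit <- fit_dark_prior(x)
  expect_lt(abs(fit$mean + 0.622), 3 * 2.08 / sqrt(1e4))
  expect_lt(abs(sqrt(fit$var) - 2.08), 3 * 2.08 / sqrt(2 * (1e4 - 1)))
})

test_that("fit_single_line_slope is OLS of mean PEL on pitch", {
  th <- seq(-30, 30, by = 10)
  exact <- fit_single_line_slope(th, 0.3 * th - 1)
  expect_equal(exact$slope, 0.3, tolerance = 1e-12)
  expect_equal(exact$intercept, -1, tolerance = 1e-12)
  expect_equal(exact$residual_std, 0, tolerance = 1e-9)
  expect_equal(exact$n_points, 7L)

  # model-generated sweep recovers the relative-precision slope
  p <- table1_params()
  pel <- vapply(th, function(t) predict_pel(line_stimuli(t, 64), p),
                numeric(1))
  fit <- fit_single_line_slope(th, pel)
  expect_equal(fit$slope, 2.08^2 / (2.08^2 + 3.01^2), tolerance = 1e-9)

  expect_equal(fit_single_line_slope(th, rep(2, 7))$slope, 0)
  expect_error(fit_single_line_slope(rep(5, 3), 1:3), "identical")
  expect_error(fit_single_line_slope(1:3, 1:2), "equal length")
  expect_warning(fit_single_line_slope(c(0, 10), c(0, 11)), ">= 1")
})

test_that("slope-variance relation round-trips and hits published values", {
  # published regression slopes reproduce the calibrated likelihood sds
  expect_equal(sqrt(variance_from_slope(0.1415, 2.08^2)), 5.12,
               tolerance = 0.005 / 5.12)
  expect_equal(sqrt(variance_from_slope(0.3234, 2.08^2)), 3.01,
               tolerance = 0.005 / 3.01)
  # equal-reliability point
  expect_equal(variance_from_slope(0.5, 2.08^2), 2.08^2)
  expect_equal(slope_from_variances(2.08^2, 2.08^2), 0.5)
  expect_equal(slope_from_variances(2.08^2, 1e12), 0, tolerance = 1e-6)
  # exact inverse pair on (0, 1)
  set.seed(9)
  for (m in stats::runif(50, 0.01, 0.99)) {
    v <- variance_from_slope(m, 2.08^2)
    expect_equal(slope_from_variances(2.08^2, v), m, tolerance = 1e-12)
  }
  expect_error(variance_from_slope(0, 2.08^2), "no measurable effect")
  expect_warning(variance_from_slope(1.2, 2.08^2), "sign inversion")
})

test_that("sigma_vl scaling round-trips", {
  expect_equal(sigma_vl_from_length(3.01, 64), 24.08)
  expect_equal(sigma_vl_from_length(3.01, 1), 3.01)
  set.seed(2)
  for (rep in 1:20) {
    s <- stats::runif(1, 0.5, 10); l <- stats::runif(1, 1, 100)
    expect_equal(sigma_vl_from_length(s, l) / sqrt(l), s, tolerance = 1e-12)
  }
})

test_that("calibrate_trials recovers generating parameters end to end", {
  preset <- generate_matin_li_preset(seed = 404)
  trials <- simulate_observer(preset$design, preset$params)
  fit <- calibrate_trials(trials)
  # bounds set by sampling noise at this design size: 3 SE for the prior
  # moments (SE of the sd estimate ~ sigma/sqrt(2(n-1))), 10% for the
  # slope-propagated likelihood sds
  expect_lt(abs(fit$prior_fit$mean + 0.622), 3 * 2.08 / sqrt(200))
  expect_lt(abs(sqrt(fit$prior_fit$var) - 2.08), 3 * 2.08 / sqrt(2 * 199))
  expect_equal(unname(fit$params$sigma_vi[["12"]]), 5.12, tolerance = 0.10)
  expect_equal(unname(fit$params$sigma_vi[["64"]]), 3.01, tolerance = 0.10)
  # raw-trial regression is offered and lands near the same slopes
  fit_raw <- calibrate_trials(trials, regress_on = "trials")
  expect_equal(fit_raw$slope_fits[["64"]]$slope,
               fit$slope_fits[["64"]]$slope, tolerance = 0.05)
})
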