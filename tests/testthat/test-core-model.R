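test_that("visual_likelihood composes per-line likelihoods", {
  p <- table1_params()
  # single cue: identity
  one <- visual_likelihood(line_stimuli(20, 64), p)
  expect_equal(one$mean, 20)
  expect_equal(one$var, 3.01^2)
  # symmetric pitches with equal reliability average
  two <- visual_likelihood(line_stimuli(c(-10, 30), 64), p)
  expect_equal(two$mean, 10)
  # frozen grid-oracle value: two equal short lines at 20 deg
  eq2 <- visual_likelihood(line_stimuli(c(20, 20), 12), p)
  expect_equal(eq2$mean, 20, tolerance = 1e-9)
  expect_equal(eq2$var, 13.1072, tolerance = 1e-6)
  # n equal cues: variance sigma_vi^2 / n
  five <- visual_likelihood(line_stimuli(rep(5, 5), 12), p)
  expect_equal(five$var, 5.12^2 / 5)
  expect_error(visual_likelihood(line_stimuli(numeric(0), numeric(0)), p),
               "at least one")
  expect_error(visual_likelihood(line_stimuli(0, 33), p), "no sigma_vi")
})

test_that("predict_pel fuses prior and likelihoods on the per-length path", {
  p <- table1_params()
  # dark condition: the prior mean
  expect_equal(predict_pel(line_stimuli(numeric(0), numeric(0)), p), -0.622)
  # frozen grid-oracle value: two long lines pitched 20 deg
  expect_equal(predict_pel(line_stimuli(c(20, 20), 64), p), 9.451903291,
               tolerance = 1e-6)
  # sweep slope equals the relative precision of the visual cue
  th <- seq(-30, 30, by = 10)
  pel <- vapply(th, function(t) predict_pel(line_stimuli(t, 64), p),
                numeric(1))
  slope <- unname(coef(lm(pel ~ th))[2])
  expect_equal(slope, 2.08^2 / (2.08^2 + 3.01^2), tolerance = 1e-9)
  # mixed lengths must be routed to the length-scaled path
  expect_error(predict_pel(line_stimuli(c(0, 0), c(12, 64)), p),
               "predict_pel_varying")
})

test_that("posterior mean is convex in component means, variance contracts", {
  p <- table1_params()
  set.seed(73)
  for (rep in 1:50) {
    th <- stats::runif(sample(1:3, 1), -30, 30)
    post <- posterior(line_stimuli(th, 12), p)
    lo <- min(c(p$prior$mean, th)); hi <- max(c(p$prior$mean, th))
    expect_gte(post$mean, lo - 1e-9)
    expect_lte(post$mean, hi + 1e-9)
    expect_lte(post$var, p$prior$var)
    expect_lte(post$var, visual_likelihood(line_stimuli(th, 12), p)$var)
    if (hi - lo > 1e-6) {  # strictly interior when cues disagree
      expect_gt(post$mean, lo)
      expect_lt(post$mean, hi)
    }
  }
  # n equal cues: posterior precision is prior precision plus n likelihoods
  post <- posterior(line_stimuli(rep(10, 3), 64), p)
  expect_equal(post$var, 1 / (1 / 2.08^2 + 3 / 3.01^2), tolerance = 1e-12)
})

test_that("predict_pel approaches the stimulus mean as cues strengthen and
           the prior as they weaken", {
  stim <- line_stimuli(c(-10, 30), 12)
  strong <- model_params(gaussian_belief(-0.622, sd = 2.08),
                         sigma_vi = c("12" = 1e-5))
  weak <- model_params(gaussian_belief(-0.622, sd = 2.08),
                       sigma_vi = c("12" = 1e6))
  expect_equal(predict_pel(stim, strong), 10, tolerance = 1e-6)
  expect_equal(predict_pel(stim, weak), -0.622, tolerance = 1e-6)
})

test_that("length-scaled path agrees with per-length path and the oracle", {
  # same length, sigma_vl constructed to match sigma_vi exactly
  p_len <- table1_params()
  p_vl <- model_params(gaussian_belief(-0.622, sd = 2.08),
                       sigma_vl = sigma_vl_from_length(3.01, 64))
  set.seed(12)
  for (rep in 1:20) {
    th <- stats::runif(sample(1:3, 1), -30, 30)
    expect_equal(predict_pel_varying(line_stimuli(th, 64), p_vl),
                 predict_pel(line_stimuli(th, 64), p_len),
                 tolerance = 1e-9)
  }
  # mixed lengths at a common pitch: between the single-line predictions
  p_mixed <- model_params(gaussian_belief(-0.622, sd = 2.08),
                          sigma_vl = 24.08)
  long1 <- predict_pel_varying(line_stimuli(20, 64), p_mixed)
  short1 <- predict_pel_varying(line_stimuli(20, 12), p_mixed)
  both <- predict_pel_varying(line_stimuli(c(20, 20), c(64, 12)), p_mixed)
  expect_gt(both, min(long1, short1))
  expect_lt(both, 20)
  # frozen grid-oracle value: zero-pitch lines of lengths 12 and 40 leave
  # only the a(l)-governed prior pull
  expect_equal(predict_pel_varying(line_stimuli(c(0, 0), c(12, 40)),
                                   p_mixed),
               -0.448131035, tolerance = 1e-6)
  expect_error(predict_pel_varying(line_stimuli(0, 12), p_len),
               "sigma_vl")
})

test_that("a_of_l matches the simplified-form identity", {
  p <- model_params(gaussian_belief(-0.622, sd = 2.08), sigma_vl = 24.08)
  k <- 24.08^2 / 2.08^2
  expect_equal(a_of_l(64, 0, p), -0.622)                 # no lines: mu_b
  expect_equal(a_of_l(64, 2, p), -0.622 / (1 + 2 * 64 / k))
  expect_lt(abs(a_of_l(1e9, 2, p)), 1e-6)                # long-line limit
  # |a(l)| shrinks as lines are added or lengthened
  expect_gt(abs(a_of_l(12, 1, p)), abs(a_of_l(12, 2, p)))
  expect_gt(abs(a_of_l(12, 1, p)), abs(a_of_l(64, 1, p)))
  # simplified form a(l) + sum(theta)/(k/l + n) reproduces the full fusion
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(1:4, 1)
    l <- stats::runif(1, 2, 100)
    th <- stats::runif(n, -30, 30)
    simplified <- a_of_l(l, n, p) + sum(th) / (k / l + n)
    expect_equal(simplified,
                 predict_pel_varying(line_stimuli(th, l), p),
                 tolerance = 1e-9)
  }
})
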