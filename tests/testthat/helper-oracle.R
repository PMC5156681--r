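# Independent brute-force oracle: moments of a normalized product of Gaussian
# densities by grid integration. Never calls package code.
grid_product_moments <- function(means, vars, lo = -90, hi = 90,
                                 step = 0.001) {
  x <- seq(lo, hi, by = step)
  logd <- rep(0, length(x))
  for (i in seq_along(means))
    logd <- logd + stats::dnorm(x, means[i], sqrt(vars[i]), log = TRUE)
  d <- exp(logd - max(logd))
  d <- d / sum(d)
  m <- sum(x * d)
  list(mean = m, var = sum((x - m)^2 * d))
}

table1_params <- function() {
  model_params(gaussian_belief(-0.622, sd = 2.08),
               sigma_vi = c("12" = 5.12, "64" = 3.01))
}

# Small balanced trial table built in code, for io/evaluation tests.
tiny_trials <- function(seed = 11) {
  d <- experiment_design(dark_trials = 5, pitch_grid = c(-20, 0, 20),
                         lengths = c(12, 64), trials_per_condition = 4,
                         two_line_conditions = list(c(20, 20)), seed = seed)
  simulate_observer(d, table1_params())
}
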