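#' Experimental design for the simulated observer
#'
#' Describes a pitched-line eye-level experiment: dark (no-stimulus) trials,
#' single-line sweeps over a pitch grid at each line length, and two-line
#' conditions. Defaults follow the classic design: pitches -30..30 deg in
#' 10 deg steps, a short 12 deg and a long 64 deg line, and two-line
#' conditions with both lines at the same pitch. Trial counts per condition
#' are not stated by the original design description; 200 is used as the
#' calibration-scale default.
#'
#' @param dark_trials Number of dark trials (>= 1).
#' @param pitch_grid Pitches for single-line conditions, degrees.
#' @param lengths Line lengths tested, degrees.
#' @param trials_per_condition Trials per stimulus condition (>= 1).
#' @param two_line_conditions List of length-2 pitch vectors; default pairs
#'   each grid pitch with itself.
#' @param seed Integer seed recorded in the output provenance.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(dark_trials = 200,
                              pitch_grid = seq(-30, 30, by = 10),
                              lengths = c(12, 64),
                              trials_per_condition = 200,
                              two_line_conditions =
                                lapply(pitch_grid, function(p) c(p, p)),
                              seed = 1L) {
  if (dark_trials < 1L || trials_per_condition < 1L)
    stop("trial counts must be >= 1")
  if (any(lengths <= 0) || any(!is.finite(lengths)))
    stop("`lengths` must be positive and finite")
  if (any(!is.finite(pitch_grid)))
    stop("`pitch_grid` must be finite")
  if (!is.list(two_line_conditions) ||
      (length(two_line_conditions) > 0L &&
       !all(lengths(two_line_conditions) == 2L)))
    stop("`two_line_conditions` must be a list of pitch pairs")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer")
  structure(list(dark_trials = as.integer(dark_trials),
                 pitch_grid = as.numeric(pitch_grid),
                 lengths = as.numeric(lengths),
                 trials_per_condition = as.integer(trials_per_condition),
                 two_line_conditions = lapply(two_line_conditions, as.numeric),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0("<experiment_design> %d dark trials; pitches {%s} deg; ",
                     "lengths {%s} deg; %d trials/condition; %d two-line ",
                     "conditions; seed %d\n"),
              x$dark_trials, paste(x$pitch_grid, collapse = ", "),
              paste(x$lengths, collapse = ", "), x$trials_per_condition,
              length(x$two_line_conditions), x$seed))
  invisible(x)
}

#' Canonical design and calibrated parameters
#'
#' The classic two-length design together with the calibrated observer
#' parameters (prior mean -0.622 deg, prior sd 2.08 deg; likelihood sd
#' 5.12 deg for the 12 deg line and 3.01 deg for the 64 deg line), for demos,
#' tests and parameter-recovery runs.
#'
#' @param seed Seed stored in the returned design.
#' @return List with elements `design` ([experiment_design()]) and `params`
#'   ([model_params()]).
#' @export
generate_matin_li_preset <- function(seed = 1L) {
  list(design = experiment_design(seed = seed),
       params = model_params(gaussian_belief(-0.622, sd = 2.08),
                             sigma_vi = c("12" = 5.12, "64" = 3.01)))
}

new_trial_rows <- function(condition_id, pitches, length_deg, settings,
                           start_idx) {
  data.frame(condition_id = condition_id,
             n_lines = length(pitches),
             pitches = paste(pitches, collapse = ";"),
             length_deg = length_deg,
             reported_pel_deg = settings,
             trial_idx = seq_along(settings) + start_idx,
             stringsAsFactors = FALSE)
}

#' Simulate a Bayesian observer's trial table
#'
#' Generates one synthetic subject's settings for every condition of a
#' design. Each stimulated trial is drawn from the posterior for its
#' condition (probability matching: mean `mu_p`, sd `sigma_p`), dark trials
#' from the prior, with optional independent motor noise added. Deterministic
#' given the design seed; the global RNG state is left untouched.
#'
#' @param design An [experiment_design()].
#' @param params A [model_params()] with a per-length `sigma_vi` map covering
#'   the design's lengths.
#' @param response_noise_sd Motor noise sd, degrees, >= 0 (default 0).
#' @return A trial-table data frame with columns `condition_id`, `n_lines`,
#'   `pitches` (semicolon-joined degrees, empty for dark), `length_deg`
#'   (`NA` for dark), `reported_pel_deg`, `trial_idx`; attribute `seed`
#'   records provenance.
#' @examples
#' preset <- generate_matin_li_preset(seed = 7)
#' trials <- simulate_observer(preset$design, preset$params)
#' head(trials)
#' @export
simulate_observer <- function(design, params, response_noise_sd = 0) {
  if (!inherits(design, "experiment_design"))
    stop("`design` must be an experiment_design")
  if (length(response_noise_sd) != 1L || !is.finite(response_noise_sd) ||
      response_noise_sd < 0)
    stop("`response_noise_sd` must be a single number >= 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(design$seed)

  draw <- function(bel, n) {
    stats::rnorm(n, bel$mean, sqrt(bel$var)) +
      if (response_noise_sd > 0)
        stats::rnorm(n, 0, response_noise_sd) else 0
  }

  idx <- 0L
  out <- list(new_trial_rows("dark", numeric(0), NA_real_,
                             draw(params$prior, design$dark_trials), idx))
  idx <- idx + design$dark_trials
  for (l in design$lengths) {
    for (th in design$pitch_grid) {
      post <- posterior(line_stimuli(th, l), params)
      id <- sprintf("single_L%g_p%g", l, th)
      out[[length(out) + 1L]] <-
        new_trial_rows(id, th, l, draw(post, design$trials_per_condition), idx)
      idx <- idx + design$trials_per_condition
    }
    for (pair in design$two_line_conditions) {
      post <- posterior(line_stimuli(pair, l), params)
      id <- sprintf("double_L%g_p%s", l, paste(pair, collapse = "x"))
      out[[length(out) + 1L]] <-
        new_trial_rows(id, pair, l, draw(post, design$trials_per_condition),
                       idx)
      idx <- idx + design$trials_per_condition
    }
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "seed") <- design$seed
  trials
}
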