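#' Estimate the body prior from dark-trial settings
#'
#' In complete darkness the reported eye-level settings reflect the
#' body-referenced prior alone, so its parameters are simply the sample mean
#' and sample standard deviation (n - 1 denominator) of the dark settings.
#'
#' @param settings Numeric vector of dark-trial PEL settings, degrees
#'   (at least 2).
#' @return A [gaussian_belief()] for the prior. A zero sample sd (all
#'   settings identical) is degenerate and raises a warning; the returned
#'   belief then carries an sd of 0 in attribute `degenerate_sd` with
#'   `var` left at the smallest representable positive value.
#' @export
fit_dark_prior <- function(settings) {
  settings <- as.numeric(settings)
  if (length(settings) < 2L || any(!is.finite(settings)))
    stop("need at least 2 finite dark settings")
  m <- mean(settings)
  s <- stats::sd(settings)
  if (s == 0) {
    warning("dark settings have zero variance; prior sd is degenerate")
    out <- gaussian_belief(m, var = .Machine$double.xmin)
    attr(out, "degenerate_sd") <- TRUE
    return(out)
  }
  gaussian_belief(m, sd = s)
}

#' Regression of mean perceived eye level on line pitch
#'
#' Ordinary least squares of mean PEL against pitch for a single-line sweep.
#' The fitted slope measures the relative strength of the visual likelihood
#' against the body prior: under the model it equals
#' `sigma_b^2 / (sigma_b^2 + sigma_v^2)`, so it feeds directly into
#' [variance_from_slope()].
#'
#' @param pitches Line pitches, degrees; at least 2 distinct values.
#' @param mean_pel Mean PEL per pitch, degrees; same length as `pitches`.
#' @return An object of class `slope_fit`: list with `slope`, `intercept`
#'   (deg), `residual_std` (deg), `n_points`. Slopes at or above 1 are
#'   inconsistent with a valid prior/likelihood decomposition and warn.
#' @export
fit_single_line_slope <- function(pitches, mean_pel) {
  pitches <- as.numeric(pitches)
  mean_pel <- as.numeric(mean_pel)
  if (length(pitches) != length(mean_pel))
    stop("`pitches` and `mean_pel` must have equal length")
  if (length(pitches) < 2L)
    stop("need at least 2 points")
  if (length(unique(pitches)) < 2L)
    stop("all pitches identical; slope is undefined")
  fit <- stats::lm(mean_pel ~ pitches)
  cf <- unname(stats::coef(fit))
  n <- length(pitches)
  rsd <- if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L)) else 0
  out <- structure(list(slope = cf[2L], intercept = cf[1L],
                        residual_std = rsd, n_points = n),
                   class = "slope_fit")
  if (out$slope >= 1)
    warning(sprintf(paste0("fitted slope %.4f >= 1: visual cue appears ",
                           "stronger than any Bayesian weighting allows"),
                    out$slope))
  out
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> y = %.4f x + %.4f (residual sd %.4f deg, n = %d)\n",
              x$slope, x$intercept, x$residual_std, x$n_points))
  invisible(x)
}

#' Visual likelihood variance from a single-line slope
#'
#' Inverts the slope relation: given the prior variance and the fitted slope
#' `m` of mean PEL on pitch, the visual variance is
#' `| prior_var / m - prior_var |`. The absolute value guards the `m > 1`
#' case, where the algebra would go negative; such slopes are passed through
#' with a warning (they signal a sign inversion, never silently clamped).
#'
#' @param m Fitted slope, dimensionless, nonzero.
#' @param prior_var Prior variance, degrees squared, > 0.
#' @return Visual likelihood variance, degrees squared.
#' @examples
#' sqrt(variance_from_slope(0.1415, 2.08^2))  # 5.12 (short line)
#' sqrt(variance_from_slope(0.3234, 2.08^2))  # 3.01 (long line)
#' @export
variance_from_slope <- function(m, prior_var) {
  if (length(m) != 1L || !is.finite(m))
    stop("`m` must be a single finite number")
  if (m == 0)
    stop("slope is 0: the visual cue had no measurable effect, ",
         "its variance is unidentifiable")
  if (length(prior_var) != 1L || !is.finite(prior_var) || prior_var <= 0)
    stop("`prior_var` must be a single positive number")
  if (m > 1)
    warning(sprintf(paste0("slope %.4f > 1: absolute value masks a sign ",
                           "inversion inconsistent with the slope relation"),
                    m))
  abs(prior_var / m - prior_var)
}

#' Predicted single-line slope from variances
#'
#' The forward slope relation `m = sigma_b^2 / (sigma_b^2 + sigma_v^2)`:
#' the relative precision of the visual cue. Exact inverse of
#' [variance_from_slope()] on (0, 1).
#'
#' @param prior_var Prior variance, degrees squared, > 0.
#' @param visual_var Visual likelihood variance, degrees squared, > 0.
#' @return Slope in (0, 1), dimensionless.
#' @export
slope_from_variances <- function(prior_var, visual_var) {
  if (any(!is.finite(c(prior_var, visual_var))) ||
      prior_var <= 0 || visual_var <= 0)
    stop("variances must be finite and > 0")
  prior_var / (prior_var + visual_var)
}

#' Length-free noise constant from a calibrated sigma_vi
#'
#' Under the independence assumption each unit of line length contributes an
#' independent sample, so `sigma_vi = sigma_vl / sqrt(l)`; this inverts that
#' relation to recover the length-free constant from one calibrated length.
#'
#' @param sigma_vi Likelihood sd at length `length_deg`, degrees, > 0.
#' @param length_deg Line length, degrees, > 0.
#' @return `sigma_vl = sigma_vi * sqrt(length_deg)`.
#' @export
sigma_vl_from_length <- function(sigma_vi, length_deg) {
  if (any(!is.finite(c(sigma_vi, length_deg))) ||
      sigma_vi <= 0 || length_deg <= 0)
    stop("`sigma_vi` and `length_deg` must be finite and > 0")
  sigma_vi * sqrt(length_deg)
}

#' Calibrate observer parameters from a trial table
#'
#' Runs the full calibration pipeline on recorded or simulated trials:
#' the prior from dark rows (sample mean/sd), then, per line length, an OLS
#' slope of single-line PEL on pitch and the slope-variance inversion to get
#' that length's likelihood sd.
#'
#' @param trials A trial table (see [simulate_observer()] / [read_trials()]).
#' @param regress_on `"means"` (default; regress per-pitch condition means,
#'   as the single-line sweeps are analysed) or `"trials"` (raw settings).
#' @return List of class `calibration_fit`: `params` (a [model_params()] with
#'   the per-length `sigma_vi` map), `prior_fit`, `slope_fits` (one
#'   [fit_single_line_slope()] result per length), `n_dark`.
#' @export
calibrate_trials <- function(trials, regress_on = c("means", "trials")) {
  regress_on <- match.arg(regress_on)
  trials <- validate_trials(trials)
  dark <- trials[trials$n_lines == 0L, ]
  if (nrow(dark) < 2L)
    stop("need at least 2 dark trials (n_lines == 0) to fit the prior")
  prior_fit <- fit_dark_prior(dark$reported_pel_deg)

  single <- trials[trials$n_lines == 1L, ]
  if (nrow(single) == 0L)
    stop("no single-line trials to calibrate sigma_vi from")
  single$pitch <- vapply(single$pitches, function(p) parse_pitches(p)[1L],
                         numeric(1))
  slope_fits <- list()
  sigma_vi <- numeric(0)
  for (l in sort(unique(single$length_deg))) {
    sub <- single[single$length_deg == l, ]
    if (regress_on == "means") {
      agg <- stats::aggregate(reported_pel_deg ~ pitch, data = sub, FUN = mean)
      fit <- fit_single_line_slope(agg$pitch, agg$reported_pel_deg)
    } else {
      fit <- fit_single_line_slope(sub$pitch, sub$reported_pel_deg)
    }
    slope_fits[[as.character(l)]] <- fit
    sigma_vi[as.character(l)] <-
      sqrt(variance_from_slope(fit$slope, prior_fit$var))
  }
  structure(list(params = model_params(prior_fit, sigma_vi = sigma_vi),
                 prior_fit = prior_fit, slope_fits = slope_fits,
                 n_dark = nrow(dark)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> prior mean %.4f deg, sd %.4f deg (n = %d)\n",
              x$prior_fit$mean, sqrt(x$prior_fit$var), x$n_dark))
  for (l in names(x$slope_fits))
    cat(sprintf("  length %s deg: slope %.4f -> sigma_vi %.4f deg\n",
                l, x$slope_fits[[l]]$slope, x$params$sigma_vi[[l]]))
  invisible(x)
}
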