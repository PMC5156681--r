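#' Composite visual likelihood from pitched lines
#'
#' Each line contributes a Gaussian likelihood over eye level centred on its
#' pitch with a length-dependent standard deviation; the composite likelihood
#' is the normalized product. For n equal-length lines this reduces to a
#' Gaussian centred on the mean pitch with variance `sigma_vi^2 / n`.
#'
#' @param stimuli A [line_stimuli()] object (or data frame with `pitch_deg`,
#'   `length_deg`); at least one line.
#' @param params A [model_params()] object.
#' @param use_length_scaling If `TRUE`, resolve per-line noise as
#'   `sigma_vl / sqrt(l)`; otherwise look each length up in the calibrated
#'   `sigma_vi` map.
#' @return A [gaussian_belief()]: the composite visual likelihood.
#' @examples
#' p <- model_params(gaussian_belief(-0.622, sd = 2.08),
#'                   sigma_vi = c("64" = 3.01))
#' visual_likelihood(line_stimuli(c(-10, 30), 64), p)
#' @export
visual_likelihood <- function(stimuli, params, use_length_scaling = FALSE) {
  stimuli <- as_stimuli(stimuli)
  if (nrow(stimuli) == 0L)
    stop("at least one line stimulus is required")
  sds <- sigma_for_lengths(stimuli$length_deg, params, use_length_scaling)
  combine_gaussians(Map(function(m, s) gaussian_belief(m, sd = s),
                        stimuli$pitch_deg, sds))
}

#' Posterior belief over eye level
#'
#' Fuses the body prior with the composite visual likelihood. With no stimuli
#' the posterior is the prior (the dark condition). The posterior variance is
#' never larger than any component's variance, and its mean lies between the
#' prior mean and the stimulus pitches.
#'
#' @inheritParams visual_likelihood
#' @return A [gaussian_belief()] (mean and variance of the posterior).
#' @export
posterior <- function(stimuli, params, use_length_scaling = FALSE) {
  stimuli <- as_stimuli(stimuli)
  if (nrow(stimuli) == 0L) return(params$prior)
  combine_gaussians(list(params$prior,
                         visual_likelihood(stimuli, params,
                                           use_length_scaling)))
}

#' Predicted perceived eye level (per-length calibration path)
#'
#' The model's predicted mean PEL: the posterior mean after fusing the body
#' prior with the per-line likelihoods, with each line's noise taken from the
#' calibrated per-length `sigma_vi` map. All stimuli must share one length on
#' this path (the per-length form assumes constant line length); for mixed
#' lengths use [predict_pel_varying()].
#'
#' @inheritParams visual_likelihood
#' @return Predicted PEL in degrees. With zero stimuli, the prior mean.
#' @examples
#' p <- model_params(gaussian_belief(-0.622, sd = 2.08),
#'                   sigma_vi = c("64" = 3.01))
#' predict_pel(line_stimuli(c(20, 20), 64), p)  # ~9.45 deg
#' @export
predict_pel <- function(stimuli, params) {
  stimuli <- as_stimuli(stimuli)
  if (nrow(stimuli) == 0L) return(params$prior$mean)
  if (length(unique(stimuli$length_deg)) > 1L)
    stop("stimuli mix line lengths; use predict_pel_varying() ",
         "(length-scaled path) for mixed lengths")
  posterior(stimuli, params)$mean
}

#' Predicted perceived eye level (length-scaled path)
#'
#' Same fusion as [predict_pel()] but with per-line variance
#' `sigma_vl^2 / l_i`, so lines of different (or never-calibrated) lengths are
#' handled. Requires `sigma_vl`; agrees with the per-length path whenever
#' `sigma_vi = sigma_vl / sqrt(l)`.
#'
#' @inheritParams visual_likelihood
#' @return Predicted PEL in degrees.
#' @export
predict_pel_varying <- function(stimuli, params) {
  stimuli <- as_stimuli(stimuli)
  if (nrow(stimuli) == 0L) return(params$prior$mean)
  posterior(stimuli, params, use_length_scaling = TRUE)$mean
}

#' Prior-pull term a(l) of the simplified model
#'
#' In the simplified form of the prediction,
#' `mu_p = a(l) + sum(theta_i) / (k / l + n)` with `k = sigma_vl^2 /
#' sigma_b^2`, the term `a(l) = mu_b / (1 + n l / k)` carries the residual
#' pull of the body prior. It equals `mu_b` with no lines and shrinks toward
#' zero as lines are added or lengthened.
#'
#' @param length_deg Line length, degrees (> 0).
#' @param n Number of lines (>= 0).
#' @param params A [model_params()] with `sigma_vl` set.
#' @return `a(l)` in degrees.
#' @export
a_of_l <- function(length_deg, n, params) {
  if (is.null(params$sigma_vl))
    stop("`sigma_vl` is not set in params")
  if (length(length_deg) != 1L || !is.finite(length_deg) || length_deg <= 0)
    stop("`length_deg` must be a single positive number")
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a single non-negative integer")
  k <- params$sigma_vl^2 / params$prior$var
  params$prior$mean / (1 + n * length_deg / k)
}
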