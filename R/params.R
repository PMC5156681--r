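#' Pitched-line stimuli
#'
#' One or more illuminated lines on a frontoparallel wall, each described by a
#' pitch angle and an angular length. Under the geometric interpretation a
#' line pitched by `pitch_deg` implies an eye level shifted by that same angle
#' (the visual system assumes the line is vertical and attributes its tilt to
#' perspective), so the per-line visual likelihood is centred on the pitch.
#'
#' @param pitch_deg Signed pitch angles, degrees; positive pitch pulls
#'   perceived eye level upward. Recycled against `length_deg`.
#' @param length_deg Angular line lengths, degrees; strictly positive.
#' @return A data frame of class `line_stimuli` with columns `pitch_deg`,
#'   `length_deg`, one row per line.
#' @examples
#' line_stimuli(c(20, 20), 64)   # two long lines at the same pitch
#' @export
line_stimuli <- function(pitch_deg, length_deg) {
  if (length(pitch_deg) == 0L)
    return(structure(data.frame(pitch_deg = numeric(0),
                                length_deg = numeric(0)),
                     class = c("line_stimuli", "data.frame")))
  n <- max(length(pitch_deg), length(length_deg))
  pitch_deg <- rep_len(as.numeric(pitch_deg), n)
  length_deg <- rep_len(as.numeric(length_deg), n)
  if (any(!is.finite(pitch_deg)))
    stop("`pitch_deg` must be finite (degrees)")
  if (any(!is.finite(length_deg)) || any(length_deg <= 0))
    stop("`length_deg` must be finite and > 0 (degrees)")
  structure(data.frame(pitch_deg = pitch_deg, length_deg = length_deg),
            class = c("line_stimuli", "data.frame"))
}

as_stimuli <- function(x) {
  if (inherits(x, "line_stimuli")) return(x)
  if (is.data.frame(x) && all(c("pitch_deg", "length_deg") %in% names(x)))
    return(line_stimuli(x$pitch_deg, x$length_deg))
  stop("expected a line_stimuli object (see `line_stimuli()`)")
}

#' Bayesian observer parameters
#'
#' Bundles the body prior with the visual noise model. Visual noise comes in
#' two interchangeable forms:
#' * `sigma_vi`: a per-length map (named numeric vector, names = line length
#'   in degrees) of likelihood standard deviations, as calibrated separately
#'   for each length tested;
#' * `sigma_vl`: a single length-free constant under the independence
#'   assumption `sigma_vi = sigma_vl / sqrt(l)`, enabling extrapolation to
#'   lengths never tested.
#'
#' The per-length map is the default prediction path ([predict_pel()]); the
#' length-scaled path ([predict_pel_varying()]) is opt-in, since the
#' square-root scaling grows questionable for long lines. Both may be stored;
#' each prediction route uses exactly one.
#'
#' @param prior A [gaussian_belief()]: the body prior (dark-condition belief).
#' @param sigma_vi Optional named numeric vector mapping line length (deg,
#'   as names) to likelihood standard deviation (deg).
#' @param sigma_vl Optional single positive number: length-free visual noise
#'   constant, units deg * sqrt(deg).
#' @return An object of class `model_params`.
#' @examples
#' model_params(gaussian_belief(-0.622, sd = 2.08),
#'              sigma_vi = c("12" = 5.12, "64" = 3.01))
#' @export
model_params <- function(prior, sigma_vi = NULL, sigma_vl = NULL) {
  if (!is_belief(prior) || !prior$informative)
    stop("`prior` must be an informative gaussian_belief")
  if (is.null(sigma_vi) && is.null(sigma_vl))
    stop("supply at least one of `sigma_vi` (per-length map) or `sigma_vl`")
  if (!is.null(sigma_vi)) {
    if (!is.numeric(sigma_vi) || is.null(names(sigma_vi)) ||
        any(!nzchar(names(sigma_vi))))
      stop("`sigma_vi` must be a named numeric vector (names = length in deg)")
    lens <- suppressWarnings(as.numeric(names(sigma_vi)))
    if (any(is.na(lens)) || any(lens <= 0))
      stop("`sigma_vi` names must be positive line lengths in degrees")
    if (any(!is.finite(sigma_vi)) || any(sigma_vi <= 0))
      stop("`sigma_vi` values must be finite and > 0")
  }
  if (!is.null(sigma_vl)) {
    if (!is.numeric(sigma_vl) || length(sigma_vl) != 1L ||
        !is.finite(sigma_vl) || sigma_vl <= 0)
      stop("`sigma_vl` must be a single finite positive number")
    sigma_vl <- as.numeric(sigma_vl)
  }
  structure(list(prior = prior, sigma_vi = sigma_vi, sigma_vl = sigma_vl),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> prior: mean %.4f deg, sd %.4f deg\n",
              x$prior$mean, sqrt(x$prior$var)))
  if (!is.null(x$sigma_vi))
    cat("  sigma_vi:",
        paste(sprintf("%.3f deg @ %s deg", x$sigma_vi, names(x$sigma_vi)),
              collapse = ", "), "\n")
  if (!is.null(x$sigma_vl))
    cat(sprintf("  sigma_vl: %.3f (length-free)\n", x$sigma_vl))
  invisible(x)
}

# Resolve the likelihood sd for each stimulus length.
# use_length_scaling = TRUE takes the sigma_vl / sqrt(l) route.
sigma_for_lengths <- function(lengths, params, use_length_scaling = FALSE) {
  if (use_length_scaling) {
    if (is.null(params$sigma_vl))
      stop("`sigma_vl` is not set; supply it to use length scaling")
    return(params$sigma_vl / sqrt(lengths))
  }
  if (is.null(params$sigma_vi))
    stop("no per-length `sigma_vi` map in params; ",
         "use predict_pel_varying()/length scaling with `sigma_vl`")
  known <- as.numeric(names(params$sigma_vi))
  idx <- vapply(lengths, function(l) {
    j <- which(abs(known - l) < 1e-9)
    if (length(j) == 0L)
      stop(sprintf(paste0("no sigma_vi calibrated for line length %g deg ",
                          "(known: %s); use the length-scaled path"),
                   l, paste(known, collapse = ", ")), call. = FALSE)
    j[1L]
  }, integer(1))
  unname(params$sigma_vi[idx])
}
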