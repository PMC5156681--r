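#' Matin-Li behavioural model parameters
#'
#' Constants of the behavioural model
#' `PEL = a + k1 * sum(theta_i) / (k2 / l + n)` fitted by Matin and Li
#' directly to data. `a` is per-length in the published fit (the short- and
#' long-line columns differ) while `k1`, `k2` are shared, so `a` is stored as
#' a named vector keyed by line length in degrees.
#'
#' @param a Named numeric vector of intercepts, degrees; names = line length
#'   in degrees (a single unnamed value is accepted and applied to every
#'   length).
#' @param k1 Dimensionless gain.
#' @param k2 Length-like constant, degrees (> 0), so `k2 / l` is
#'   dimensionless.
#' @return Object of class `matin_li_params`.
#' @examples
#' matin_li_published_params()
#' @export
matin_li_params <- function(a, k1, k2) {
  if (!is.numeric(a) || length(a) < 1L || any(!is.finite(a)))
    stop("`a` must be finite numeric (degrees)")
  if (length(a) > 1L || !is.null(names(a))) {
    if (is.null(names(a)) || any(!nzchar(names(a))))
      stop("per-length `a` must be named by line length in degrees")
    lens <- suppressWarnings(as.numeric(names(a)))
    if (any(is.na(lens)) || any(lens <= 0))
      stop("names of `a` must be positive line lengths in degrees")
  }
  if (length(k1) != 1L || !is.finite(k1))
    stop("`k1` must be a single finite number")
  if (length(k2) != 1L || !is.finite(k2) || k2 <= 0)
    stop("`k2` must be a single positive number")
  structure(list(a = a, k1 = as.numeric(k1), k2 = as.numeric(k2)),
            class = "matin_li_params")
}

#' Published Matin-Li constants
#'
#' The constants fitted to the original two-line data: shared `k1 = 0.51`,
#' `k2 = 19.44`, with per-length intercepts `a = -0.29` (12 deg lines) and
#' `a = -4.61` (64 deg lines).
#'
#' @return A [matin_li_params()] object.
#' @export
matin_li_published_params <- function() {
  matin_li_params(a = c("12" = -0.29, "64" = -4.61), k1 = 0.51, k2 = 19.44)
}

resolve_ml_a <- function(params, length_deg) {
  a <- params$a
  if (is.null(names(a))) return(unname(a))
  known <- as.numeric(names(a))
  j <- which(abs(known - length_deg) < 1e-9)
  if (length(j) == 0L)
    stop(sprintf("no Matin-Li intercept `a` for line length %g deg (known: %s)",
                 length_deg, paste(known, collapse = ", ")))
  unname(a[j[1L]])
}

#' Perceived eye level under the Matin-Li behavioural model
#'
#' Evaluates `PEL = a + k1 * sum(theta_i) / (k2 / l + n)` for `n` lines of a
#' common length. The prediction is linear in the pitch sum with slope
#' `k1 / (k2 / l + n)`; as `k2 / l` vanishes it tends to the averaging form
#' `a + k1 * mean(theta_i)`.
#'
#' @param pitches Line pitches, degrees (may be empty: the dark prediction is
#'   `a`, given a length to resolve the per-length intercept).
#' @param length_deg Line length, degrees, > 0.
#' @param params A [matin_li_params()] object.
#' @return Predicted PEL, degrees.
#' @examples
#' predict_pel_matin_li(c(20, 20), 12, matin_li_published_params())  # ~5.35
#' @export
predict_pel_matin_li <- function(pitches, length_deg, params) {
  if (!inherits(params, "matin_li_params"))
    stop("`params` must be a matin_li_params object")
  if (length(length_deg) != 1L || !is.finite(length_deg) || length_deg <= 0)
    stop("`length_deg` must be a single positive number")
  pitches <- as.numeric(pitches)
  if (any(!is.finite(pitches)))
    stop("`pitches` must be finite")
  n <- length(pitches)
  resolve_ml_a(params, length_deg) +
    params$k1 * sum(pitches) / (params$k2 / length_deg + n)
}
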