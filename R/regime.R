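#' Additive-versus-averaging regime analysis
#'
#' Quantifies how two identical cues combine relative to one. For each pitch
#' on a grid, the single-line PEL shift from the prior and the two-line shift
#' (both lines at that pitch) are computed; the two-line shift is regressed on
#' the *sum* of the two single-line shifts. A slope near 1 means combined
#' cues add (weak, high-variance cues); near 0.5 means they average (strong,
#' low-variance cues). Shifts are measured from the prior mean so a nonzero
#' prior does not bias the slope.
#'
#' The model is exactly linear in pitch, so the regression slope equals the
#' closed-form shift ratio
#' `(sigma_vi^2 + sigma_b^2) / (sigma_vi^2 + 2 sigma_b^2)`, which lies
#' strictly in (0.5, 1) for finite positive variances and increases with the
#' cue's variance (weaker cues are more additive).
#'
#' @param params A [model_params()] with a `sigma_vi` entry for `length_deg`
#'   (or `sigma_vl` with `use_length_scaling = TRUE`).
#' @param length_deg Line length, degrees.
#' @param pitch_grid Pitches to probe, degrees; at least 2 distinct values.
#' @param use_length_scaling Resolve noise via `sigma_vl / sqrt(l)` instead of
#'   the per-length map.
#' @param cutoffs Heuristic classification thresholds on the slope:
#'   `additive` (at or above: "additive-like") and `averaging` (at or below:
#'   "averaging-like"); in between is "intermediate". Labels only; the raw
#'   slope is always reported.
#' @return Object of class `regime_report`: `slope` (regression),
#'   `shift_ratio` (closed form), `classification`, `cutoffs`, and `table`
#'   with per-pitch single shift, combined shift, their sum and average.
#' @examples
#' p <- model_params(gaussian_belief(-0.622, sd = 2.08),
#'                   sigma_vi = c("12" = 5.12, "64" = 3.01))
#' combination_regime(p, 12)
#' @export
combination_regime <- function(params, length_deg,
                               pitch_grid = seq(-30, 30, by = 10),
                               use_length_scaling = FALSE,
                               cutoffs = c(additive = 0.9, averaging = 0.6)) {
  pitch_grid <- as.numeric(pitch_grid)
  if (length(unique(pitch_grid)) < 2L)
    stop("`pitch_grid` must contain at least 2 distinct pitches")
  if (!all(c("additive", "averaging") %in% names(cutoffs)))
    stop("`cutoffs` needs named elements `additive` and `averaging`")

  predict1 <- if (use_length_scaling) predict_pel_varying else predict_pel
  mu_b <- params$prior$mean
  single <- vapply(pitch_grid, function(th)
    predict1(line_stimuli(th, length_deg), params), numeric(1)) - mu_b
  combined <- vapply(pitch_grid, function(th)
    predict1(line_stimuli(c(th, th), length_deg), params), numeric(1)) - mu_b

  tab <- data.frame(pitch_deg = pitch_grid,
                    single_shift = single,
                    combined_shift = combined,
                    sum_of_singles = 2 * single,
                    average_of_singles = single)
  slope <- unname(stats::coef(stats::lm(combined ~ I(2 * single)))[2L])

  sv <- sigma_for_lengths(length_deg, params, use_length_scaling)
  ratio <- (sv^2 + params$prior$var) / (sv^2 + 2 * params$prior$var)

  classification <- if (slope >= cutoffs[["additive"]]) "additive-like"
    else if (slope <= cutoffs[["averaging"]]) "averaging-like"
    else "intermediate"

  structure(list(slope = slope, shift_ratio = ratio,
                 classification = classification, cutoffs = cutoffs,
                 length_deg = length_deg, table = tab),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf(paste0("<regime_report> length %g deg: combined-vs-sum slope ",
                     "%.4f (%s)\n"), x$length_deg, x$slope, x$classification))
  cat(sprintf("  closed-form shift ratio %.4f; cutoffs: additive-like >= %g, averaging-like <= %g\n",
              x$shift_ratio, x$cutoffs[["additive"]], x$cutoffs[["averaging"]]))
  invisible(x)
}
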