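#' Standard error of estimate between predictions and observations
#'
#' Aggregate prediction error in degrees. The default is the population RMSE
#' `sqrt(sum((obs - pred)^2) / n)`; the `"regression"` convention divides by
#' `n - 2` instead (two fitted parameters), for comparability with regression
#' residual standard errors.
#'
#' @param predicted,observed Equal-length, nonempty numeric vectors, degrees.
#' @param method `"population"` (divide by n, default) or `"regression"`
#'   (divide by n - 2; requires n > 2).
#' @return Nonnegative error in degrees; 0 iff predictions are exact.
#' @export
standard_error_of_estimate <- function(predicted, observed,
                                       method = c("population",
                                                  "regression")) {
  method <- match.arg(method)
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  if (length(predicted) == 0L)
    stop("`predicted` and `observed` must be nonempty")
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("inputs must be finite")
  ss <- sum((observed - predicted)^2)
  denom <- if (method == "population") length(observed)
    else {
      if (length(observed) <= 2L)
        stop("regression convention needs more than 2 points")
      length(observed) - 2L
    }
  sqrt(ss / denom)
}

#' Side-by-side Bayesian versus Matin-Li comparison
#'
#' Scores both models against a trial table. By default each condition is
#' collapsed to its mean observed PEL (as condition means are the published
#' unit of comparison); `by = "trial"` scores every trial. The Bayesian
#' prediction uses the per-length posterior mean; the Matin-Li prediction
#' evaluates its behavioural equation. Dark conditions have no line length,
#' so the Matin-Li prediction is `NA` there and those rows are excluded from
#' its error (the Bayesian dark prediction is the prior mean).
#'
#' @param trials A trial table (see [simulate_observer()], [read_trials()]).
#' @param bayes A [model_params()] object.
#' @param ml A [matin_li_params()] object.
#' @param by `"condition"` (default) or `"trial"`.
#' @param see_method Passed to [standard_error_of_estimate()].
#' @return Object of class `pel_model_comparison`: `table` (one row per
#'   condition or trial with observed and both predictions) and `see` (named
#'   vector: `bayes`, `matin_li`, degrees).
#' @export
compare_models <- function(trials, bayes, ml, by = c("condition", "trial"),
                           see_method = "population") {
  by <- match.arg(by)
  trials <- validate_trials(trials)
  if (nrow(trials) == 0L)
    return(structure(list(table = trials[0, ],
                          see = c(bayes = NA_real_, matin_li = NA_real_)),
                     class = "pel_model_comparison"))
  if (any(trials$n_lines > 0L & !is.finite(trials$length_deg)))
    stop("stimulated conditions are missing a line length")

  key <- c("condition_id", "n_lines", "pitches", "length_deg")
  conds <- unique(trials[, key])
  conds$observed_pel_deg <- vapply(seq_len(nrow(conds)), function(i) {
    sel <- trials$condition_id == conds$condition_id[i]
    mean(trials$reported_pel_deg[sel])
  }, numeric(1))
  preds <- lapply(seq_len(nrow(conds)), function(i) {
    pitches <- parse_pitches(conds$pitches[i])
    l <- conds$length_deg[i]
    b <- if (length(pitches) == 0L) bayes$prior$mean
      else predict_pel(line_stimuli(pitches, l), bayes)
    m <- if (length(pitches) == 0L || !is.finite(l)) NA_real_
      else predict_pel_matin_li(pitches, l, ml)
    c(b, m)
  })
  conds$bayes_pred_deg <- vapply(preds, `[`, numeric(1), 1L)
  conds$matin_li_pred_deg <- vapply(preds, `[`, numeric(1), 2L)
  rownames(conds) <- NULL

  if (by == "trial") {
    i <- match(trials$condition_id, conds$condition_id)
    tab <- cbind(trials[, c(key, "reported_pel_deg", "trial_idx")],
                 bayes_pred_deg = conds$bayes_pred_deg[i],
                 matin_li_pred_deg = conds$matin_li_pred_deg[i])
    names(tab)[names(tab) == "reported_pel_deg"] <- "observed_pel_deg"
    rownames(tab) <- NULL
  } else {
    tab <- conds
  }
  ok_ml <- is.finite(tab$matin_li_pred_deg)
  see <- c(bayes = standard_error_of_estimate(tab$bayes_pred_deg,
                                              tab$observed_pel_deg,
                                              method = see_method),
           matin_li = if (any(ok_ml))
             standard_error_of_estimate(tab$matin_li_pred_deg[ok_ml],
                                        tab$observed_pel_deg[ok_ml],
                                        method = see_method)
           else NA_real_)
  structure(list(table = tab, see = see), class = "pel_model_comparison")
}

#' @export
print.pel_model_comparison <- function(x, ...) {
  cat(sprintf(paste0("<pel_model_comparison> %d rows; SEE: Bayesian %.3f ",
                     "deg, Matin-Li %.3f deg\n"),
              nrow(x$table), x$see[["bayes"]], x$see[["matin_li"]]))
  invisible(x)
}
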