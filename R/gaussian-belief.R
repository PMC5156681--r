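#' Gaussian belief over eye-level elevation
#'
#' A belief about eye level is represented as a Gaussian over elevation angle,
#' in signed degrees (0 = true eye level, positive = upward). The same
#' container holds the body-referenced prior measured in darkness, a visual
#' likelihood implied by one or more pitched lines, and the fused posterior.
#'
#' An *uninformative* belief (zero precision, the limit of infinite variance)
#' is represented explicitly via `uninformative_belief()` rather than by a
#' large sentinel variance, so that limiting behaviour is exact.
#'
#' @param mean Mean elevation, degrees. Must be finite.
#' @param sd Standard deviation, degrees. Exactly one of `sd`/`var` is given.
#' @param var Variance, degrees squared. Must be strictly positive.
#' @return An object of class `gaussian_belief` with fields `mean`, `var`
#'   (degrees squared) and `informative` (logical).
#' @examples
#' prior <- gaussian_belief(-0.622, sd = 2.08)
#' prior
#' @seealso [combine_gaussians()], [uninformative_belief()]
#' @export
gaussian_belief <- function(mean, sd = NULL, var = NULL) {
  if (is.null(var) == is.null(sd))
    stop("supply exactly one of `sd` or `var`")
  if (is.null(var)) {
    if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
      stop("`sd` must be a single finite positive number (degrees)")
    var <- sd^2
  }
  if (!is.numeric(var) || length(var) != 1L || !is.finite(var) || var <= 0)
    stop("`var` must be a single finite positive number (degrees^2)")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("`mean` must be a single finite number (degrees)")
  structure(list(mean = as.numeric(mean), var = as.numeric(var),
                 informative = TRUE),
            class = "gaussian_belief")
}

#' @rdname gaussian_belief
#' @export
uninformative_belief <- function() {
  structure(list(mean = NA_real_, var = Inf, informative = FALSE),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  if (!x$informative) {
    cat("<gaussian_belief> uninformative (precision 0)\n")
  } else {
    cat(sprintf("<gaussian_belief> mean %.4f deg, sd %.4f deg\n",
                x$mean, sqrt(x$var)))
  }
  invisible(x)
}

is_belief <- function(x) inherits(x, "gaussian_belief")

#' Fuse Gaussian beliefs by multiplication of densities
#'
#' Multiplying Gaussian densities yields another Gaussian whose precision is
#' the sum of the input precisions and whose mean is the precision-weighted
#' average of the input means. This is the single primitive behind every
#' prediction in the package: the posterior over eye level is the fusion of
#' the body prior with the per-line visual likelihoods.
#'
#' Uninformative beliefs contribute zero precision and drop out exactly.
#'
#' @param beliefs A list of [gaussian_belief()] objects (a single belief is
#'   also accepted). At least one must be informative.
#' @return A `gaussian_belief`: the normalized product.
#' @examples
#' prior <- gaussian_belief(-0.622, sd = 2.08)
#' lik <- gaussian_belief(10, sd = 3.01)
#' combine_gaussians(list(prior, lik))
#' @export
combine_gaussians <- function(beliefs) {
  if (is_belief(beliefs)) beliefs <- list(beliefs)
  if (!is.list(beliefs) || length(beliefs) == 0L)
    stop("`beliefs` must be a non-empty list of gaussian_belief objects")
  if (!all(vapply(beliefs, is_belief, logical(1))))
    stop("`beliefs` must contain only gaussian_belief objects")
  informative <- vapply(beliefs, function(b) b$informative, logical(1))
  if (!any(informative))
    stop("all beliefs are uninformative: the product carries no information")
  means <- vapply(beliefs[informative], function(b) b$mean, numeric(1))
  precs <- 1 / vapply(beliefs[informative], function(b) b$var, numeric(1))
  gaussian_belief(sum(means * precs) / sum(precs), var = 1 / sum(precs))
}
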