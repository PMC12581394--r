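#' Deming (errors-in-variables) regression
#'
#' Fits a straight line when both measurement methods carry error, as in
#' method-comparison studies of quantitative assay values (e.g. TMB measured
#' by two platforms). The slope is the closed-form maximum-likelihood
#' solution for a given ratio `lambda` of the error variances
#' (var(error in y) / var(error in x)); `lambda = 1` gives orthogonal
#' regression. As `lambda` grows without bound the fit converges to ordinary
#' least squares of y on x.
#'
#' @param x,y paired numeric measurements (at least 3 complete pairs).
#' @param variance_ratio ratio of the y-error variance to the x-error
#'   variance (default 1).
#' @return An object of class `deming`: coefficients (intercept, slope),
#'   Pearson correlation `r`, `n`, and the variance ratio.
#' @examples
#' fit <- deming_regression(1:10, 2 * (1:10) + 1)
#' coef(fit)  # intercept 1, slope 2
#' @export
deming_regression <- function(x, y, variance_ratio = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 finite pairs are required", call. = FALSE)
  if (length(y) != n) stop("x and y must be paired", call. = FALSE)
  if (!is.numeric(variance_ratio) || variance_ratio <= 0)
    stop("variance_ratio must be positive", call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0)
    stop("degenerate fit: both variables have zero variance", call. = FALSE)
  lambda <- variance_ratio
  slope <- if (sxy == 0) {
    # no covariance: vertical/horizontal degeneracy; fall back on the
    # axis with variance
    if (sxx == 0) Inf else 0
  } else {
    (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)
  r <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  structure(list(coefficients = c(intercept = intercept, slope = slope),
                 r = r, n = n, variance_ratio = lambda,
                 x_mean = mean(x), y_mean = mean(y)),
            class = "deming")
}

#' @export
coef.deming <- function(object, ...) object$coefficients

#' @export
print.deming <- function(x, ...) {
  cat(sprintf("Deming regression (error-variance ratio %g, n = %d)\n",
              x$variance_ratio, x$n))
  cat(sprintf("  slope = %.4f, intercept = %.4f, Pearson r = %.4f\n",
              x$coefficients[["slope"]], x$coefficients[["intercept"]], x$r))
  invisible(x)
}

#' @export
predict.deming <- function(object, newdata, ...) {
  if (missing(newdata)) stop("newdata (x values) required", call. = FALSE)
  x <- if (is.list(newdata)) newdata$x else newdata
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * x
}
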