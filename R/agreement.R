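#' Binomial proportion confidence intervals
#'
#' Interval estimates for a single proportion. The default is the Wilson
#' score interval without continuity correction; the exact Clopper-Pearson
#' interval and the continuity-corrected Wilson interval are also available.
#' All bounds are clipped to \[0, 1\].
#'
#' For x = n the Wilson lower limit has the closed form n / (n + z^2) and the
#' Clopper-Pearson lower limit is (alpha/2)^(1/n); these identities are used
#' as exact checks in the test suite.
#'
#' @param successes number of successes (0 <= successes <= trials).
#' @param trials number of trials (>= 1).
#' @param method one of `"wilson"`, `"clopper_pearson"`, `"wilson_cc"`.
#' @param level two-sided confidence level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(successes, trials,
                          method = c("wilson", "clopper_pearson", "wilson_cc"),
                          level = 0.95) {
  method <- match.arg(method)
  if (length(trials) != 1L || is.na(trials) || trials < 1)
    stop("trials must be a single count >= 1 (proportion undefined otherwise)",
         call. = FALSE)
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  x <- successes; n <- trials
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    if (method == "wilson") {
      denom <- 1 + z^2 / n
      center <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      low <- center - half
      high <- center + half
    } else { # wilson_cc
      low <- if (x == 0) 0 else
        (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
        (2 * (n + z^2))
      high <- if (x == n) 1 else
        (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
        (2 * (n + z^2))
    }
  }
  c(low = max(0, low), high = min(1, high))
}

arm_levels <- c("ccd1", "ccd2", "fcd")

match_arm <- function(arm) {
  arm <- tolower(as.character(arm))
  if (!arm %in% arm_levels)
    stop("unknown arm '", arm, "' (expected one of ",
         paste(arm_levels, collapse = ", "), ")", call. = FALSE)
  arm
}

#' Pairwise percent agreement between two assay arms
#'
#' Positive percent agreement (PPA) is the proportion of reference-positive
#' samples on which the test arm is also positive; negative percent agreement
#' (NPA) conditions on reference-negative samples; overall percent agreement
#' (OPA) on all samples. The table must contain no invalid calls (see
#' [filter_invalid()]).
#'
#' @param table a valid-only [paired_call_table].
#' @param reference_arm,test_arm arm names among `"ccd1"`, `"ccd2"`, `"fcd"`.
#' @param polarity `"PPA"`, `"NPA"` or `"OPA"`.
#' @param ci_method passed to [proportion_ci()].
#' @param level confidence level.
#' @return An object of class `agreement_estimate`: a list with the
#'   numerator, denominator, point estimate and confidence limits.
#' @examples
#' tab <- paired_call_table(1:4, c("+", "+", "-", "-"),
#'                          c("+", "+", "-", "-"), c("+", "-", "-", "-"))
#' pairwise_agreement(tab, "ccd1", "fcd", "PPA")
#' @export
pairwise_agreement <- function(table, reference_arm, test_arm,
                               polarity = c("PPA", "NPA", "OPA"),
                               ci_method = "wilson", level = 0.95) {
  polarity <- match.arg(polarity)
  table <- as_paired_call_table(table)
  stopifnot_valid_only(table)
  reference_arm <- match_arm(reference_arm)
  test_arm <- match_arm(test_arm)
  ref <- table[[reference_arm]]
  tst <- table[[test_arm]]
  keep <- switch(polarity,
                 PPA = ref == "positive",
                 NPA = ref == "negative",
                 OPA = rep(TRUE, length(ref)))
  denominator <- sum(keep)
  if (denominator == 0L)
    stop("no reference-", if (polarity == "NPA") "negative" else "positive",
         " samples: ", polarity, " undefined", call. = FALSE)
  numerator <- sum(keep & tst == ref)
  ci <- proportion_ci(numerator, denominator, method = ci_method, level = level)
  structure(list(kind = polarity, reference_arm = reference_arm,
                 test_arm = test_arm, numerator = numerator,
                 denominator = denominator,
                 estimate = numerator / denominator,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 ci_method = ci_method, level = level),
            class = "agreement_estimate")
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("%s(%s -> %s) = %s (%s, %s)  %d/%d  [%s]\n",
              x$kind, x$reference_arm, x$test_arm,
              format_percent(x$estimate), format_percent(x$ci_low),
              format_percent(x$ci_high), x$numerator, x$denominator,
              x$ci_method))
  invisible(x)
}

# one decimal, half-up, matching the usual CDx summary-table presentation
format_percent <- function(p, digits = 1) {
  scaled <- p * 100 * 10^digits
  rounded <- floor(scaled + 0.5) / 10^digits
  paste0(formatC(rounded, format = "f", digits = digits), "%")
}
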