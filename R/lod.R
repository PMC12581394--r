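#' Dilution series container
#'
#' Replicate detection outcomes of one analyte over an increasing series of
#' concentration levels (variant frequency, copies, or percent tumor
#' content).
#'
#' @param level numeric, strictly increasing concentration levels.
#' @param detected integer, detections per level (0 <= detected <= replicates).
#' @param replicates integer, replicates tested per level (>= 1).
#' @param analyte optional analyte identifier.
#' @return A `data.frame` of class `dilution_series`.
#' @export
dilution_series <- function(level, detected, replicates, analyte = "analyte") {
  if (length(level) == 0L) stop("empty dilution series", call. = FALSE)
  if (is.unsorted(level, strictly = TRUE))
    stop("levels must be strictly increasing", call. = FALSE)
  if (any(replicates < 1)) stop("replicates must be >= 1 per level", call. = FALSE)
  if (any(detected < 0 | detected > replicates))
    stop("detected must lie in [0, replicates]", call. = FALSE)
  out <- data.frame(analyte = analyte, level = as.numeric(level),
                    detected = as.integer(detected),
                    replicates = as.integer(replicates),
                    stringsAsFactors = FALSE)
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' Limit of detection by the empirical hit-rate rule
#'
#' The limit of detection (LoD) is the lowest tested level at which at least
#' `hit_rate_threshold` (default 95%) of replicates produced a positive
#' result, with the additional monotone-tail requirement that every higher
#' tested level also meets the threshold; this guards against declaring an
#' LoD below a level where observed detection dips again. If no level
#' qualifies the LoD is undefined (reported as above the highest tested
#' level).
#'
#' @param series a [dilution_series].
#' @param hit_rate_threshold minimum per-level hit rate (default 0.95).
#' @return An object of class `lod_estimate`: `lod` (a tested level or `NA`),
#'   and the per-level hit rates.
#' @examples
#' s <- dilution_series(c(5, 8, 10), c(18, 19, 20), 20)
#' estimate_lod(s)  # LoD = 8 (19/20 = 95%)
#' @export
estimate_lod <- function(series, hit_rate_threshold = 0.95) {
  if (!inherits(series, "dilution_series"))
    series <- dilution_series(series$level, series$detected, series$replicates,
                              analyte = series$analyte %||% "analyte")
  hit_rate <- series$detected / series$replicates
  # a level qualifies when it and every level above it meet the threshold
  tail_ok <- rev(cumall(rev(hit_rate >= hit_rate_threshold)))
  lod <- if (any(tail_ok)) series$level[which(tail_ok)[1]] else NA_real_
  structure(list(lod = lod, defined = !is.na(lod),
                 max_tested = max(series$level),
                 threshold = hit_rate_threshold,
                 levels = data.frame(level = series$level,
                                     detected = series$detected,
                                     replicates = series$replicates,
                                     hit_rate = hit_rate)),
            class = "lod_estimate")
}

cumall <- function(x) cumprod(x) > 0

#' @export
print.lod_estimate <- function(x, ...) {
  if (x$defined) cat(sprintf("LoD = %g (hit-rate threshold %.0f%%)\n",
                             x$lod, 100 * x$threshold))
  else cat(sprintf("LoD undefined: > %g (no level sustained the %.0f%% hit rate)\n",
                   x$max_tested, 100 * x$threshold))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Limit of blank: false-positive rates on analyte-free samples
#'
#' Pools false-positive calls over a panel of wild-type (analyte-free)
#' samples per variant class and reports the rate with an exact binomial
#' (Clopper-Pearson) interval. Classes with zero calls report a rate of 0
#' with the one-sided exact upper bound `1 - (1 - level)^(1/n)`.
#'
#' @param panel data.frame with columns `variant_class`,
#'   `false_positive_calls`, `opportunities` (rows may repeat classes; they
#'   are pooled).
#' @param level confidence level (default 0.95).
#' @return A `data.frame` of class `lob_estimate`: per-class calls,
#'   opportunities, rate and confidence limits.
#' @export
estimate_lob <- function(panel, level = 0.95) {
  need <- c("variant_class", "false_positive_calls", "opportunities")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(panel) == 0L) stop("empty blank panel", call. = FALSE)
  if (any(panel$false_positive_calls > panel$opportunities))
    stop("false_positive_calls cannot exceed opportunities", call. = FALSE)
  agg <- stats::aggregate(
    cbind(calls = false_positive_calls, opportunities = opportunities) ~
      variant_class, data = panel, FUN = sum)
  if (any(agg$opportunities == 0))
    stop("zero opportunities for class ",
         paste(agg$variant_class[agg$opportunities == 0], collapse = ", "),
         ": rate undefined", call. = FALSE)
  ci <- t(mapply(function(x, n) {
    if (x == 0) c(0, 1 - (1 - level)^(1 / n))
    else proportion_ci(x, n, method = "clopper_pearson", level = level)
  }, agg$calls, agg$opportunities))
  out <- data.frame(variant_class = agg$variant_class, calls = agg$calls,
                    opportunities = agg$opportunities,
                    rate = agg$calls / agg$opportunities,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    stringsAsFactors = FALSE)
  class(out) <- c("lob_estimate", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
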