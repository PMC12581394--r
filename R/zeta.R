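#' @section Cell encoding:
#' Internally a valid-only paired call table collapses to counts over the
#' eight (ccd1, ccd2, fcd) call patterns; every agreement proportion and
#' every zeta difference is a function of these counts only.
#' @noRd
cell_counts <- function(table) {
  stopifnot_valid_only(table)
  i <- 4L * (table$ccd1 == "positive") + 2L * (table$ccd2 == "positive") +
    (table$fcd == "positive") + 1L
  counts <- tabulate(i, nbins = 8L)
  names(counts) <- vapply(0:7, function(k) {
    paste0(ifelse(bitwAnd(k, c(4L, 2L, 1L)) > 0L, "+", "-"), collapse = "")
  }, character(1))
  counts
}

# rows of an 8 x B count matrix selected by call pattern; `counts` may be a
# vector (one table) or a matrix (bootstrap replicates in columns)
cell_sum <- function(counts, rows) {
  if (is.matrix(counts)) colSums(counts[rows, , drop = FALSE])
  else sum(counts[rows])
}

zeta_names <- c("zeta_ppa1", "zeta_ppa2", "zeta_npa1", "zeta_npa2")

# the four zeta differences from cell counts; returns a 4 x B matrix (or a
# named length-4 vector for a count vector); NA where a denominator is zero
zetas_from_counts <- function(counts) {
  idx <- function(c1, c2, f) { # each argument 0, 1 or NA (= either)
    keep <- rep(TRUE, 8)
    bits <- cbind(c1 = bitwAnd(0:7, 4L) > 0L, c2 = bitwAnd(0:7, 2L) > 0L,
                  f = bitwAnd(0:7, 1L) > 0L)
    for (j in seq_len(3)) {
      want <- c(c1, c2, f)[j]
      if (!is.na(want)) keep <- keep & (bits[, j] == (want == 1))
    }
    which(keep)
  }
  z <- function(num_a, num_b, den) {
    d <- cell_sum(counts, den)
    out <- (cell_sum(counts, num_a) - cell_sum(counts, num_b)) / d
    out[d == 0] <- NA_real_
    out
  }
  res <- rbind(
    zeta_ppa1 = z(idx(1, 1, NA), idx(1, NA, 1), idx(1, NA, NA)),
    zeta_ppa2 = z(idx(1, 1, NA), idx(NA, 1, 1), idx(NA, 1, NA)),
    zeta_npa1 = z(idx(0, 0, NA), idx(0, NA, 0), idx(0, NA, NA)),
    zeta_npa2 = z(idx(0, 0, NA), idx(NA, 0, 0), idx(NA, 0, NA)))
  if (!is.matrix(counts)) res <- res[, 1]
  res
}

#' Agreement differences (zeta) between comparator replicates and the FCD
#'
#' In a comparator-anchored concordance study the follow-on test (FCD) is
#' judged against the internal consistency of the comparator (CCD) itself.
#' Four differences are formed: zetaPPA1 = PPA_C1C2 - PPA_C1F,
#' zetaPPA2 = PPA_C2C1 - PPA_C2F, zetaNPA1 = NPA_C1C2 - NPA_C1F and
#' zetaNPA2 = NPA_C2C1 - NPA_C2F, where PPA_C1F is the proportion of CCD1
#' positive samples on which the FCD is positive, and so on. A zeta near zero
#' means the FCD agrees with a comparator replicate as well as the second
#' comparator replicate does.
#'
#' @param table a valid-only [paired_call_table].
#' @return An object of class `zeta_set`: a list of the four zetas, each with
#'   a `point` value (confidence limits are added by [bootstrap_zeta_ci()] or
#'   [zeta_newcombe_ci()]).
#' @export
zeta_differences <- function(table) {
  table <- as_paired_call_table(table)
  z <- zetas_from_counts(cell_counts(table))
  if (anyNA(z)) {
    bad <- zeta_names[is.na(z)]
    stop("undefined zeta (empty reference denominator): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(lapply(stats::setNames(zeta_names, zeta_names), function(nm)
    list(point = z[[nm]], ci_low = NA_real_, ci_high = NA_real_,
         method = NA_character_)),
    class = "zeta_set", n = nrow(table))
}

#' Percentile-bootstrap confidence intervals for the zeta differences
#'
#' Resamples whole sample triples (rows) with replacement and takes the
#' empirical alpha/2 and 1-alpha/2 quantiles of each zeta over the bootstrap
#' replicates (linear interpolation). Because every zeta is a function of the
#' counts of the eight (ccd1, ccd2, fcd) call patterns, row resampling is
#' performed by drawing the pattern counts of each replicate from a
#' multinomial distribution over the observed pattern frequencies, which is
#' distributionally identical to resampling rows. Replicates on which a zeta
#' is undefined (an empty reference denominator) are skipped for that zeta
#' and counted.
#'
#' @param table a valid-only [paired_call_table].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed; recorded in the result.
#' @return A `zeta_set` whose elements carry `point`, `ci_low`, `ci_high`
#'   and `method = "percentile_bootstrap"`; attributes record `n_boot`,
#'   `seed`, `level` and the per-zeta count of skipped replicates.
#' @export
bootstrap_zeta_ci <- function(table, n_boot = 1000, level = 0.95, seed = NULL) {
  table <- as_paired_call_table(table)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  counts <- cell_counts(table)
  n <- sum(counts)
  point <- zetas_from_counts(counts)
  if (anyNA(point))
    stop("undefined zeta (empty reference denominator): ",
         paste(zeta_names[is.na(point)], collapse = ", "), call. = FALSE)
  boot_counts <- with_seed(seed, stats::rmultinom(n_boot, n, counts / n))
  zb <- zetas_from_counts(boot_counts) # 4 x n_boot, NA where undefined
  n_skipped <- rowSums(is.na(zb))
  if (any(n_skipped > n_boot / 2))
    stop("bootstrap unstable for this margin: >50% of replicates undefined for ",
         paste(zeta_names[n_skipped > n_boot / 2], collapse = ", "),
         call. = FALSE)
  alpha <- 1 - level
  out <- lapply(stats::setNames(zeta_names, zeta_names), function(nm) {
    q <- stats::quantile(zb[nm, ], c(alpha / 2, 1 - alpha / 2),
                         na.rm = TRUE, names = FALSE, type = 7)
    list(point = point[[nm]], ci_low = q[1], ci_high = q[2],
         method = "percentile_bootstrap")
  })
  structure(out, class = "zeta_set", n = n, n_boot = n_boot, seed = seed,
            level = level, n_skipped = stats::setNames(n_skipped, zeta_names))
}

#' @export
print.zeta_set <- function(x, ...) {
  cat("zeta differences (CCD replicate agreement minus FCD agreement):\n")
  for (nm in names(x)) {
    z <- x[[nm]]
    cat(sprintf("  %-9s %+7.4f", sub("zeta_", "zeta", toupper(nm)), z$point))
    if (!is.na(z$ci_low))
      cat(sprintf("  [%+7.4f, %+7.4f] (%s)", z$ci_low, z$ci_high, z$method))
    cat("\n")
  }
  invisible(x)
}

#' Newcombe method-10 interval for a paired difference of proportions
#'
#' Confidence interval for the difference between the positive (or negative)
#' call proportions of two assay arms measured on the same samples, following
#' method 10 of Newcombe (1998) for paired data: continuity-corrected Wilson
#' score limits for each marginal proportion are combined by the
#' square-and-add construction, with a correction for the within-pair
#' correlation estimated (with continuity correction) from the paired 2x2
#' table. Used for unenriched designs (e.g. wild-type selection claims
#' enrolled without enrichment) where the bootstrap is replaced by a
#' closed-form interval.
#'
#' @param table a valid-only [paired_call_table].
#' @param arm_a,arm_b the two arms being compared.
#' @param polarity `"PPA"` compares the positive-call proportions, `"NPA"`
#'   the negative-call proportions.
#' @param level confidence level.
#' @return A list with `diff`, `low`, `high` and the paired 2x2 counts.
#' @references Newcombe, R. G. (1998). Improved confidence intervals for the
#'   difference between binomial proportions based on paired data.
#'   Statistics in Medicine 17, 2635-2650.
#' @export
newcombe10_paired_diff_ci <- function(table, arm_a, arm_b,
                                      polarity = c("PPA", "NPA"),
                                      level = 0.95) {
  polarity <- match.arg(polarity)
  table <- as_paired_call_table(table)
  stopifnot_valid_only(table)
  arm_a <- match_arm(arm_a); arm_b <- match_arm(arm_b)
  target <- if (polarity == "PPA") "positive" else "negative"
  a_hit <- table[[arm_a]] == target
  b_hit <- table[[arm_b]] == target
  n <- length(a_hit)
  if (n < 2) stop("fewer than 2 paired observations", call. = FALSE)
  e <- sum(a_hit & b_hit); f <- sum(a_hit & !b_hit)
  g <- sum(!a_hit & b_hit); h <- sum(!a_hit & !b_hit)
  ci <- newcombe10_from_counts(e, f, g, h, level = level)
  c(ci, list(counts = c(both = e, a_only = f, b_only = g, neither = h)))
}

# literal method-10 arithmetic on the paired 2x2 counts
newcombe10_from_counts <- function(e, f, g, h, level = 0.95) {
  n <- e + f + g + h
  p1 <- (e + f) / n
  p2 <- (e + g) / n
  d <- p1 - p2
  w1 <- proportion_ci(e + f, n, method = "wilson_cc", level = level)
  w2 <- proportion_ci(e + g, n, method = "wilson_cc", level = level)
  r1 <- e + f; r2 <- g + h; c1 <- e + g; c2 <- f + h
  phi <- if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) 0 else {
    num <- e * h - f * g
    if (num > 0) num <- max(num - n / 2, 0)
    num / sqrt(as.numeric(r1) * r2 * c1 * c2)
  }
  dl1 <- p1 - w1[["low"]]; du1 <- w1[["high"]] - p1
  dl2 <- p2 - w2[["low"]]; du2 <- w2[["high"]] - p2
  low <- d - sqrt(max(dl1^2 - 2 * phi * dl1 * du2 + du2^2, 0))
  high <- d + sqrt(max(du1^2 - 2 * phi * du1 * dl2 + dl2^2, 0))
  list(diff = d, low = max(-1, low), high = min(1, high))
}

#' Newcombe method-10 confidence intervals for all four zetas
#'
#' Each zeta is a paired difference of proportions on the samples in its
#' reference denominator: e.g. zetaPPA1 restricts to CCD1-positive samples
#' and compares the positive-call proportions of CCD2 and FCD. The method-10
#' interval is applied to each restricted comparison.
#'
#' @inheritParams bootstrap_zeta_ci
#' @return A `zeta_set` with `method = "newcombe10"` confidence limits.
#' @export
zeta_newcombe_ci <- function(table, level = 0.95) {
  table <- as_paired_call_table(table)
  stopifnot_valid_only(table)
  spec <- list(
    zeta_ppa1 = list(ref = "ccd1", ref_val = "positive", a = "ccd2", b = "fcd", pol = "PPA"),
    zeta_ppa2 = list(ref = "ccd2", ref_val = "positive", a = "ccd1", b = "fcd", pol = "PPA"),
    zeta_npa1 = list(ref = "ccd1", ref_val = "negative", a = "ccd2", b = "fcd", pol = "NPA"),
    zeta_npa2 = list(ref = "ccd2", ref_val = "negative", a = "ccd1", b = "fcd", pol = "NPA"))
  out <- lapply(spec, function(s) {
    sub <- table[table[[s$ref]] == s$ref_val, , drop = FALSE]
    if (nrow(sub) < 2)
      stop("undefined zeta: fewer than 2 samples in the ", s$ref, " ",
           s$ref_val, " denominator", call. = FALSE)
    ci <- newcombe10_paired_diff_ci(sub, s$a, s$b, polarity = s$pol,
                                    level = level)
    list(point = ci$diff, ci_low = ci$low, ci_high = ci$high,
         method = "newcombe10")
  })
  structure(out, class = "zeta_set", n = nrow(table), level = level)
}

#' Non-inferiority decision from zeta confidence intervals
#'
#' The observed margin epsilon is the maximum upper 95% confidence limit over
#' the zetas on each side: epsilon1 over the predictive-side zetas and
#' epsilon0 over the selective-side zetas. The follow-on test achieves the
#' targeted non-inferiority level on a side when epsilon is strictly below
#' the target margin delta; equality fails. By default the predictive side is
#' mapped to the PPA zetas and the selective side to the NPA zetas; the
#' mapping can be swapped for claims that select on a negative result.
#'
#' @param zetas a `zeta_set` with confidence limits on all four zetas.
#' @param delta1 target margin for the predictive side.
#' @param delta0 target margin for the selective side.
#' @param predictive_side `"ppa"` (default) or `"npa"`: which pair of zetas
#'   carries the predictive claim.
#' @return An object of class `noninferiority_result` with `epsilon1`,
#'   `epsilon0`, the margins and the pass booleans.
#' @export
noninferiority_decision <- function(zetas, delta1, delta0,
                                    predictive_side = c("ppa", "npa")) {
  predictive_side <- match.arg(predictive_side)
  uppers <- vapply(zetas, function(z) z$ci_high, numeric(1))
  if (anyNA(uppers))
    stop("incomplete input: missing confidence limit on ",
         paste(names(uppers)[is.na(uppers)], collapse = ", "), call. = FALSE)
  ppa_max <- max(uppers[c("zeta_ppa1", "zeta_ppa2")])
  npa_max <- max(uppers[c("zeta_npa1", "zeta_npa2")])
  epsilon1 <- if (predictive_side == "ppa") ppa_max else npa_max
  epsilon0 <- if (predictive_side == "ppa") npa_max else ppa_max
  structure(list(epsilon1 = epsilon1, epsilon0 = epsilon0,
                 delta1 = delta1, delta0 = delta0,
                 predictive_side = predictive_side,
                 pass_predictive = epsilon1 < delta1,
                 pass_selective = epsilon0 < delta0,
                 pass_overall = epsilon1 < delta1 && epsilon0 < delta0),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  verdict <- function(p) if (p) "PASS" else "FAIL"
  cat(sprintf("predictive: epsilon1 = %.4f vs delta1 = %.4f  -> %s\n",
              x$epsilon1, x$delta1, verdict(x$pass_predictive)))
  cat(sprintf("selective:  epsilon0 = %.4f vs delta0 = %.4f  -> %s\n",
              x$epsilon0, x$delta0, verdict(x$pass_selective)))
  cat("overall non-inferiority:", verdict(x$pass_overall), "\n")
  invisible(x)
}
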