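#' Prevalence-adjusted agreement for enriched cohorts
#'
#' Concordance cohorts for rare biomarkers are enriched with pre-test
#' positive samples, so raw PPA/NPA do not describe the intended-use
#' population. The adjustment estimates the joint distribution of
#' (comparator call, FCD call) separately within each enrollment stratum,
#' reweights the strata to an assumed population prevalence of the pre-test
#' marker by the law of total probability, and recomputes agreement from the
#' reweighted joint distribution by Bayes' theorem:
#' PPA_adj = P(F+ and C+) / P(C+) and NPA_adj = P(F- and C-) / P(C-).
#'
#' The within-stratum joint distribution is assumed transportable to the
#' population. When the supplied prevalence equals the observed fraction of
#' pre-test-positive samples, the adjustment reproduces the unadjusted
#' pooled estimates exactly.
#'
#' @param table a valid-only [paired_call_table] whose rows carry
#'   `pretest_positive` / `pretest_negative` strata.
#' @param population_prevalence assumed population prevalence of the
#'   pre-test marker, strictly inside (0, 1).
#' @param comparator which comparator arm anchors the agreement
#'   (default `"ccd1"`).
#' @return An object of class `prevalence_adjusted`: adjusted PPA and NPA,
#'   the stratum weights used, and the observed sample prevalence.
#' @export
prevalence_adjust <- function(table, population_prevalence,
                              comparator = "ccd1") {
  table <- as_paired_call_table(table)
  stopifnot_valid_only(table)
  comparator <- match_arm(comparator)
  if (!is.numeric(population_prevalence) ||
      population_prevalence <= 0 || population_prevalence >= 1)
    stop("population prevalence must lie strictly inside (0, 1): ",
         "adjustment undefined otherwise", call. = FALSE)
  strata <- c("pretest_positive", "pretest_negative")
  for (s in strata)
    if (!any(table$stratum == s))
      stop("stratum unobserved: no rows with stratum '", s, "'", call. = FALSE)
  joint <- function(sub) { # P(comparator call, fcd call) within a stratum
    c_pos <- sub[[comparator]] == "positive"
    f_pos <- sub$fcd == "positive"
    n <- nrow(sub)
    c(pp = sum(c_pos & f_pos), pn = sum(c_pos & !f_pos),
      np = sum(!c_pos & f_pos), nn = sum(!c_pos & !f_pos)) / n
  }
  w <- c(pretest_positive = population_prevalence,
         pretest_negative = 1 - population_prevalence)
  p <- w[["pretest_positive"]] *
    joint(table[table$stratum == "pretest_positive", , drop = FALSE]) +
    w[["pretest_negative"]] *
    joint(table[table$stratum == "pretest_negative", , drop = FALSE])
  p_cpos <- p[["pp"]] + p[["pn"]]
  p_cneg <- p[["np"]] + p[["nn"]]
  if (p_cpos == 0 || p_cneg == 0)
    stop("adjusted agreement undefined: reweighted comparator ",
         if (p_cpos == 0) "positive" else "negative",
         " probability is zero", call. = FALSE)
  structure(list(
    ppa_adjusted = p[["pp"]] / p_cpos,
    npa_adjusted = p[["nn"]] / p_cneg,
    population_prevalence = population_prevalence,
    sample_prevalence = mean(table$stratum == "pretest_positive"),
    comparator = comparator,
    joint = p), class = "prevalence_adjusted")
}

#' @export
print.prevalence_adjusted <- function(x, ...) {
  cat(sprintf("prevalence-adjusted agreement vs %s (population prevalence %.3f):\n",
              x$comparator, x$population_prevalence))
  cat(sprintf("  PPA_adj = %s   NPA_adj = %s\n",
              format_percent(x$ppa_adjusted), format_percent(x$npa_adjusted)))
  invisible(x)
}
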