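#' Fit a comparator-anchored concordance analysis
#'
#' One call runs the full follow-on CDx concordance analysis on a paired
#' call table: invalid-call handling, the eight pairwise agreements between
#' the comparator replicates and the follow-on test, the four zeta
#' differences with confidence intervals (percentile bootstrap by default,
#' Newcombe method 10 for unenriched designs), the epsilon-versus-delta
#' non-inferiority decision, and (optionally) prevalence-adjusted agreement
#' for enriched cohorts.
#'
#' @param calls a [paired_call_table] or a data.frame coercible to one.
#' @param delta1,delta0 target non-inferiority margins for the predictive and
#'   selective sides (study-specific; 0.05 by default).
#' @param invalid_policy how invalid calls are handled before analysis; the
#'   primary analysis excludes them (see [filter_invalid()]).
#' @param zeta_ci_method `"percentile_bootstrap"` (default) or
#'   `"newcombe10"`.
#' @param n_boot bootstrap replicates when the bootstrap method is used.
#' @param level two-sided confidence level for all intervals.
#' @param ci_method single-proportion CI method for the agreement estimates
#'   (see [proportion_ci()]).
#' @param prevalence optional population prevalence of the pre-test marker;
#'   when supplied (and the table carries enrollment strata) adjusted PPA/NPA
#'   are included.
#' @param predictive_side mapping of the predictive claim to the PPA- or
#'   NPA-side zetas (see [noninferiority_decision()]).
#' @param seed integer seed for the bootstrap; recorded in the result.
#' @return An object of class `cdx_concordance` with components
#'   `agreements` (named list of [pairwise_agreement()] results),
#'   `zetas` (a `zeta_set` with CIs), `noninferiority`
#'   (a `noninferiority_result`), `prevalence_adjusted` (or `NULL`),
#'   `filter_summary`, and `config`.
#' @examples
#' cohort <- simulate_concordance_cohort(concordance_sim_spec(
#'   n_samples = 400, seed = 7))
#' fit <- concordance(cohort, delta1 = 0.05, delta0 = 0.05,
#'                    n_boot = 200, seed = 7)
#' print(fit)
#' @export
concordance <- function(calls, delta1 = 0.05, delta0 = 0.05,
                        invalid_policy = "exclude",
                        zeta_ci_method = c("percentile_bootstrap", "newcombe10"),
                        n_boot = 1000, level = 0.95, ci_method = "wilson",
                        prevalence = NULL,
                        predictive_side = c("ppa", "npa"), seed = NULL) {
  zeta_ci_method <- match.arg(zeta_ci_method)
  predictive_side <- match.arg(predictive_side)
  calls <- as_paired_call_table(calls)
  table <- filter_invalid(calls, policy = invalid_policy)
  filter_summary <- attr(table, "invalid_summary")

  arms <- list(c1c2 = c("ccd1", "ccd2"), c1f = c("ccd1", "fcd"),
               c2c1 = c("ccd2", "ccd1"), c2f = c("ccd2", "fcd"))
  agreements <- list()
  for (pol in c("PPA", "NPA")) {
    for (nm in names(arms)) {
      agreements[[paste0(tolower(pol), "_", nm)]] <-
        pairwise_agreement(table, arms[[nm]][1], arms[[nm]][2], polarity = pol,
                           ci_method = ci_method, level = level)
    }
  }
  agreements$opa_c1f <- pairwise_agreement(table, "ccd1", "fcd", "OPA",
                                           ci_method = ci_method, level = level)

  zetas <- if (zeta_ci_method == "percentile_bootstrap")
    bootstrap_zeta_ci(table, n_boot = n_boot, level = level, seed = seed)
  else zeta_newcombe_ci(table, level = level)

  noninf <- noninferiority_decision(zetas, delta1 = delta1, delta0 = delta0,
                                    predictive_side = predictive_side)

  prev_adj <- if (!is.null(prevalence))
    prevalence_adjust(table, prevalence) else NULL

  config <- list(delta1 = delta1, delta0 = delta0,
                 invalid_policy = invalid_policy,
                 zeta_ci_method = zeta_ci_method, n_boot = n_boot,
                 level = level, ci_method = ci_method,
                 prevalence = prevalence, predictive_side = predictive_side,
                 seed = seed)
  structure(list(agreements = agreements, zetas = zetas,
                 noninferiority = noninf, prevalence_adjusted = prev_adj,
                 filter_summary = filter_summary, n = nrow(table),
                 config = config, config_hash = config_hash(config)),
            class = "cdx_concordance")
}

#' @export
print.cdx_concordance <- function(x, ...) {
  cat(sprintf("Comparator-anchored concordance analysis (n = %d analyzable)\n",
              x$n))
  fs <- x$filter_summary
  cat(sprintf("  invalid policy: %s (%d dropped, %d recoded of %d input rows)\n",
              fs$policy, fs$n_dropped, fs$n_recoded, fs$n_input))
  a <- x$agreements
  fmt <- function(e) sprintf("%s (%s, %s) %d/%d",
                             format_percent(e$estimate),
                             format_percent(e$ci_low),
                             format_percent(e$ci_high),
                             e$numerator, e$denominator)
  cat("  PPA C1F:", fmt(a$ppa_c1f), "  NPA C1F:", fmt(a$npa_c1f), "\n")
  cat("  PPA C1C2:", fmt(a$ppa_c1c2), " NPA C1C2:", fmt(a$npa_c1c2), "\n")
  print(x$zetas)
  print(x$noninferiority)
  if (!is.null(x$prevalence_adjusted)) print(x$prevalence_adjusted)
  invisible(x)
}

#' @export
summary.cdx_concordance <- function(object, ...) {
  a <- object$agreements
  tab <- do.call(rbind, lapply(names(a), function(nm) {
    e <- a[[nm]]
    data.frame(comparison = nm, kind = e$kind, reference = e$reference_arm,
               test = e$test_arm, numerator = e$numerator,
               denominator = e$denominator, estimate = e$estimate,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  }))
  structure(list(agreements = tab, zetas = object$zetas,
                 noninferiority = object$noninferiority,
                 prevalence_adjusted = object$prevalence_adjusted,
                 filter_summary = object$filter_summary, n = object$n,
                 config = object$config),
            class = "summary.cdx_concordance")
}

#' @export
print.summary.cdx_concordance <- function(x, ...) {
  cat("Agreement estimates:\n")
  tab <- x$agreements
  tab$estimate <- format_percent(tab$estimate)
  tab$ci_low <- format_percent(tab$ci_low)
  tab$ci_high <- format_percent(tab$ci_high)
  print(tab, row.names = FALSE)
  print(x$zetas)
  print(x$noninferiority)
  if (!is.null(x$prevalence_adjusted)) print(x$prevalence_adjusted)
  invisible(x)
}
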