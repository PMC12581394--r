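#' Variance components of a within-lab precision panel
#'
#' Decomposes the variability of replicate quantitative measurements (e.g.
#' TMB or MSI locus counts for one panel member) into operator/instrument,
#' reagent-lot, between-run and within-run (residual) components, following
#' the method-of-moments nested/crossed ANOVA used in CLSI EP05-style
#' precision studies. The design assumed is operator/instrument crossed with
#' reagent lot, runs nested within each operator-by-lot cell, and replicates
#' within runs (any of the outer factors may have a single level, in which
#' case its component is zero and flagged).
#'
#' Negative method-of-moments estimates are truncated to zero before
#' totaling, so the reported total variance is the sum of the reported
#' components. The percent coefficient of variation is
#' `100 * total_sd / mean` and is an error when the mean is zero.
#'
#' @param panel data.frame in long format with a numeric `value` column and
#'   factor columns for the design.
#' @param value,operator,lot,run names of the columns holding the
#'   measurement, the operator/instrument level, the reagent lot and the
#'   run (day) identifier. Runs are treated as nested within operator x lot.
#' @return An object of class `variance_decomposition`: per-component
#'   variances, `total_variance`, `total_sd`, `mean`, `cv_percent`, and
#'   `flags` naming single-level factors.
#' @export
variance_components <- function(panel, value = "value",
                                operator = "operator", lot = "lot",
                                run = "run") {
  for (col in c(value, operator, lot, run))
    if (!col %in% names(panel))
      stop("missing column '", col, "'", call. = FALSE)
  y <- panel[[value]]
  if (!is.numeric(y) || anyNA(y)) stop("values must be numeric and complete",
                                       call. = FALSE)
  op <- as.factor(panel[[operator]])
  lo <- as.factor(panel[[lot]])
  cell <- interaction(op, lo, drop = TRUE)
  rn <- interaction(cell, as.factor(panel[[run]]), drop = TRUE)
  N <- length(y)
  a <- nlevels(op); b <- nlevels(lo)
  n_runs <- nlevels(rn)
  if (min(table(rn)) < 2)
    stop("at least 2 replicates are required at the innermost (within-run) level",
         call. = FALSE)
  flags <- character(0)
  if (a == 1) flags <- c(flags, "operator: single level, component fixed at 0")
  if (b == 1) flags <- c(flags, "lot: single level, component fixed at 0")

  grand <- mean(y)
  ms <- function(f) { # between-group mean square of factor f (balanced)
    k <- nlevels(f)
    if (k < 2) return(NA_real_)
    gm <- tapply(y, f, mean)
    gn <- tapply(y, f, length)
    sum(gn * (gm - grand)^2) / (k - 1)
  }
  # within-run residual
  run_mean <- stats::ave(y, rn)
  df_e <- N - n_runs
  ms_e <- sum((y - run_mean)^2) / df_e
  # between runs within cells
  cell_mean <- stats::ave(y, cell)
  k_cells <- nlevels(cell)
  df_run <- n_runs - k_cells
  ms_run <- if (df_run > 0) {
    per_run <- tapply(y, rn, mean)
    per_run_n <- tapply(y, rn, length)
    per_run_cell <- tapply(as.character(cell), rn, `[`, 1)
    cmeans <- tapply(y, cell, mean)
    sum(per_run_n * (per_run - cmeans[per_run_cell])^2) / df_run
  } else NA_real_

  r_rep <- N / n_runs        # average replicates per run
  n_per_op <- N / a
  n_per_lot <- N / b

  sigma_e <- ms_e
  sigma_run <- if (!is.na(ms_run)) max((ms_run - ms_e) / r_rep, 0) else 0
  base <- sigma_e + r_rep * sigma_run # E[MS] floor for the outer factors
  ms_op <- ms(op); ms_lot <- ms(lo)
  sigma_op <- if (a > 1) max((ms_op - base) / n_per_op, 0) else 0
  sigma_lot <- if (b > 1) max((ms_lot - base) / n_per_lot, 0) else 0

  components <- c(operator_instrument = sigma_op, reagent_lot = sigma_lot,
                  between_run = sigma_run, within_run = sigma_e)
  total_variance <- sum(components)
  total_sd <- sqrt(total_variance)
  if (grand == 0)
    stop("%CV undefined: the panel mean is zero", call. = FALSE)
  structure(list(components = components, total_variance = total_variance,
                 total_sd = total_sd, mean = grand,
                 cv_percent = 100 * total_sd / abs(grand),
                 n = N, n_runs = n_runs, flags = flags),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("within-lab variance decomposition:\n")
  comp <- data.frame(component = names(x$components),
                     variance = unname(x$components),
                     sd = sqrt(unname(x$components)))
  print(comp, row.names = FALSE)
  cat(sprintf("total SD = %.4g, mean = %.4g, %%CV = %.2f%%\n",
              x$total_sd, x$mean, x$cv_percent))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Positive call rate per variant-frequency bucket
#'
#' Precision of qualitative variant detection summarized over nested
#' variant-frequency (VF) buckets: for each lower bound, the rate pools the
#' detected replicate calls over all tracked variants whose target VF is at
#' or above the bound. Empty buckets are reported as `NA` (undefined), not
#' zero.
#'
#' @param calls data.frame with one row per tracked variant: `vf` (target
#'   VF in percent), `detected` (replicate calls detected), `replicates`.
#' @param buckets numeric lower bounds in percent (default 5, 8, 10, 15).
#' @return A `data.frame` with bucket, detected, opportunities, call rate.
#' @export
vf_bucket_precision <- function(calls, buckets = c(5, 8, 10, 15)) {
  need <- c("vf", "detected", "replicates")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(calls$detected > calls$replicates))
    stop("detected cannot exceed replicates", call. = FALSE)
  out <- do.call(rbind, lapply(sort(buckets), function(bound) {
    keep <- calls$vf >= bound
    det <- sum(calls$detected[keep]); opp <- sum(calls$replicates[keep])
    data.frame(bucket = paste0(">=", bound, "%"), vf_min = bound,
               detected = det, opportunities = opp,
               call_rate = if (opp > 0) det / opp else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
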