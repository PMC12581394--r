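#' DNA-input concordance between a challenge and a control condition
#'
#' Compares qualitative calls made at a challenge DNA input level with calls
#' from the control (reference) input on the same samples, per alteration
#' class, reporting PPA/NPA with exact (Clopper-Pearson) intervals. For
#' quantitative TMB, the summary statistic is the mean over samples of the
#' absolute percent difference between challenge and control TMB, with a
#' percentile-bootstrap upper confidence bound (resampling samples).
#'
#' @param control_calls,challenge_calls data.frames with columns `sample_id`,
#'   `class` (alteration class) and `call` (positive/negative); rows are
#'   paired by (sample_id, class) and must match one-to-one.
#' @param tmb_control,tmb_challenge optional paired numeric TMB vectors
#'   (same length, same sample order).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates for the TMB bound (default 2000).
#' @param seed optional integer seed for the bootstrap.
#' @return An object of class `input_study`: per-class agreement table and,
#'   when TMB vectors are supplied, `tmb_abs_pct_diff` (mean) and
#'   `tmb_abs_pct_diff_ci_upper`.
#' @export
input_concordance <- function(control_calls, challenge_calls,
                              tmb_control = NULL, tmb_challenge = NULL,
                              level = 0.95, n_boot = 2000, seed = NULL) {
  for (df in list(control_calls, challenge_calls)) {
    miss <- setdiff(c("sample_id", "class", "call"), names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- function(df) paste(df$sample_id, df$class, sep = "\r")
  control_calls <- control_calls[order(key(control_calls)), , drop = FALSE]
  challenge_calls <- challenge_calls[order(key(challenge_calls)), , drop = FALSE]
  if (nrow(control_calls) != nrow(challenge_calls) ||
      !identical(key(control_calls), key(challenge_calls)))
    stop("alignment failure: control and challenge calls are not paired ",
         "one-to-one on (sample_id, class)", call. = FALSE)
  ctrl <- normalize_call(control_calls$call, what = "control call")
  chal <- normalize_call(challenge_calls$call, what = "challenge call")
  if (any(ctrl == "invalid") || any(chal == "invalid"))
    stop("input-study calls must be positive/negative (resolve invalids first)",
         call. = FALSE)
  per_class <- do.call(rbind, lapply(unique(control_calls$class), function(cl) {
    k <- control_calls$class == cl
    ref_pos <- ctrl[k] == "positive"
    agree <- ctrl[k] == chal[k]
    row <- function(kind, keep) {
      den <- sum(keep)
      if (den == 0)
        return(data.frame(class = cl, kind = kind, numerator = NA_integer_,
                          denominator = 0L, estimate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_))
      num <- sum(agree[keep])
      ci <- proportion_ci(num, den, method = "clopper_pearson", level = level)
      data.frame(class = cl, kind = kind, numerator = num, denominator = den,
                 estimate = num / den, ci_low = ci[["low"]],
                 ci_high = ci[["high"]])
    }
    rbind(row("PPA", ref_pos), row("NPA", !ref_pos))
  }))
  rownames(per_class) <- NULL

  tmb <- NULL
  if (!is.null(tmb_control) || !is.null(tmb_challenge)) {
    if (length(tmb_control) != length(tmb_challenge))
      stop("tmb_control and tmb_challenge must be paired vectors of equal length",
           call. = FALSE)
    if (any(tmb_control == 0))
      stop("percent difference undefined: control TMB contains zero", call. = FALSE)
    pct <- 100 * abs(tmb_challenge - tmb_control) / tmb_control
    m <- length(pct)
    boot_means <- with_seed(seed, {
      idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = m)
      colMeans(matrix(pct[idx], nrow = m))
    })
    tmb <- list(tmb_abs_pct_diff = mean(pct),
                tmb_abs_pct_diff_ci_upper =
                  stats::quantile(boot_means, level, names = FALSE, type = 7),
                n = m, n_boot = n_boot, seed = seed)
  }
  structure(list(agreement = per_class, tmb = tmb, level = level),
            class = "input_study")
}

#' @export
print.input_study <- function(x, ...) {
  cat("DNA-input concordance (challenge vs control):\n")
  tab <- x$agreement
  tab$estimate <- ifelse(is.na(tab$estimate), "undefined",
                         format_percent(tab$estimate))
  print(tab[, c("class", "kind", "numerator", "denominator", "estimate",
                "ci_low", "ci_high")], row.names = FALSE)
  if (!is.null(x$tmb))
    cat(sprintf("TMB mean absolute %% difference = %.2f%% (upper %.0f%% bound %.2f%%)\n",
                x$tmb$tmb_abs_pct_diff, 100 * x$level,
                x$tmb$tmb_abs_pct_diff_ci_upper))
  invisible(x)
}
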