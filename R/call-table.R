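#' Paired qualitative call tables
#'
#' A paired call table holds, per sample, the three qualitative results of a
#' follow-on companion diagnostic (FCD) concordance study: two replicates of
#' the comparator companion diagnostic (`ccd1`, `ccd2`) and one FCD call
#' (`fcd`), each one of `"positive"`, `"negative"` or `"invalid"`, together
#' with the enrollment stratum of the sample (`"pretest_positive"`,
#' `"pretest_negative"` or `"unenriched"`).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param ccd1,ccd2,fcd qualitative calls; accepted spellings are
#'   positive/negative/invalid, pos/neg, or +/- (case-insensitive).
#' @param stratum enrollment stratum per sample; defaults to `"unenriched"`.
#' @param tumor_type optional character vector of tumor types.
#' @return A `data.frame` of class `paired_call_table`.
#' @examples
#' paired_call_table(c("s1", "s2"), c("pos", "neg"), c("pos", "neg"),
#'                   c("pos", "pos"))
#' @export
paired_call_table <- function(sample_id, ccd1, ccd2, fcd,
                              stratum = "unenriched", tumor_type = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (n < 1L) stop("a paired call table needs at least one row", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  ccd1 <- normalize_call(ccd1, n, "ccd1")
  ccd2 <- normalize_call(ccd2, n, "ccd2")
  fcd  <- normalize_call(fcd, n, "fcd")
  stratum <- normalize_stratum(rep_len(stratum, n))
  out <- data.frame(sample_id = sample_id, ccd1 = ccd1, ccd2 = ccd2,
                    fcd = fcd, stratum = stratum,
                    stringsAsFactors = FALSE)
  if (!is.null(tumor_type)) out$tumor_type <- rep_len(as.character(tumor_type), n)
  class(out) <- c("paired_call_table", "data.frame")
  out
}

call_levels <- c("positive", "negative", "invalid")
stratum_levels <- c("pretest_positive", "pretest_negative", "unenriched")

normalize_call <- function(x, n = length(x), what = "call") {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("pos", "+")] <- "positive"
  x[x %in% c("neg", "-")] <- "negative"
  bad <- !(x %in% call_levels)
  if (any(bad))
    stop("unknown ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected positive/negative/invalid)", call. = FALSE)
  rep_len(x, n)
}

normalize_stratum <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("pos", "positive")] <- "pretest_positive"
  x[x %in% c("neg", "negative")] <- "pretest_negative"
  bad <- !(x %in% stratum_levels)
  if (any(bad))
    stop("unknown stratum value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  x
}

#' Coerce a data frame to a paired call table
#'
#' @param x a data.frame with columns `sample_id`, `ccd1`, `ccd2`, `fcd` and
#'   optionally `stratum` and `tumor_type`.
#' @return A `paired_call_table`.
#' @export
as_paired_call_table <- function(x) {
  if (inherits(x, "paired_call_table")) return(x)
  need <- c("sample_id", "ccd1", "ccd2", "fcd")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  paired_call_table(x$sample_id, x$ccd1, x$ccd2, x$fcd,
                    stratum = if ("stratum" %in% names(x)) x$stratum else "unenriched",
                    tumor_type = x[["tumor_type"]])
}

#' Resolve invalid calls before concordance analysis
#'
#' The primary analysis excludes any sample with an invalid result on either
#' assay; best- and worst-case sensitivity analyses instead recode invalid
#' calls to the value that maximizes (resp. minimizes) within-sample
#' agreement. Recoding is deterministic: invalid calls are resolved in arm
#' order (ccd1, ccd2, fcd), each to the majority (best case) or minority
#' (worst case) value among the already-resolved calls of that row, with
#' negative (best) / positive-then-negative (worst) used when no resolved
#' call constrains the choice.
#'
#' @param table a [paired_call_table].
#' @param policy `"exclude"` (drop rows containing an invalid call),
#'   `"best_case"` or `"worst_case"`.
#' @return A `paired_call_table` with no invalid calls and an
#'   `"invalid_summary"` attribute listing the number of rows dropped or
#'   recoded under the chosen policy.
#' @export
filter_invalid <- function(table, policy = c("exclude", "best_case", "worst_case")) {
  policy <- match.arg(policy)
  table <- as_paired_call_table(table)
  arms <- c("ccd1", "ccd2", "fcd")
  has_invalid <- Reduce(`|`, lapply(arms, function(a) table[[a]] == "invalid"))
  if (policy == "exclude") {
    out <- table[!has_invalid, , drop = FALSE]
    if (nrow(out) == 0L)
      stop("no analyzable samples: every row contains an invalid call",
           call. = FALSE)
    summary <- list(policy = policy, n_input = nrow(table),
                    n_dropped = sum(has_invalid), n_recoded = 0L)
  } else {
    out <- table
    n_recoded <- 0L
    for (i in which(has_invalid)) {
      calls <- unlist(out[i, arms], use.names = TRUE)
      for (a in arms[calls == "invalid"]) {
        resolved <- calls[calls != "invalid"]
        n_pos <- sum(resolved == "positive")
        n_neg <- sum(resolved == "negative")
        calls[a] <- if (policy == "best_case") {
          if (n_pos > n_neg) "positive" else "negative"
        } else {
          if (n_pos > n_neg) "negative"
          else if (n_neg > n_pos) "positive"
          else if (n_pos == 0L) "positive" else "negative"
        }
        n_recoded <- n_recoded + 1L
      }
      out[i, arms] <- as.list(calls)
    }
    summary <- list(policy = policy, n_input = nrow(table),
                    n_dropped = 0L, n_recoded = n_recoded)
  }
  rownames(out) <- NULL
  attr(out, "invalid_summary") <- summary
  out
}

stopifnot_valid_only <- function(table) {
  arms <- c("ccd1", "ccd2", "fcd")
  if (any(vapply(arms, function(a) any(table[[a]] == "invalid"), logical(1))))
    stop("table contains invalid calls; apply filter_invalid() first",
         call. = FALSE)
  invisible(table)
}
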