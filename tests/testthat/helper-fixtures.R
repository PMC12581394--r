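# Build a paired call table from call-pattern counts. Patterns are
# three-character strings over {p, n, i} giving (ccd1, ccd2, fcd),
# e.g. "ppp" = all positive, "ppn" = FCD negative.
table_from_patterns <- function(patterns, counts, stratum = "unenriched") {
  stopifnot(length(patterns) == length(counts))
  expand <- rep(patterns, counts)
  if (length(stratum) == length(patterns) && length(patterns) > 1)
    stratum <- rep(stratum, counts)
  decode <- function(ch) c(p = "positive", n = "negative", i = "invalid")[[ch]]
  calls <- t(vapply(strsplit(expand, ""), function(chs)
    vapply(chs, decode, character(1)), character(3)))
  paired_call_table(seq_along(expand), calls[, 1], calls[, 2], calls[, 3],
                    stratum = rep(stratum, length.out = length(expand)))
}

# One-decimal percent rendering used when comparing against printed tables.
format_pct <- function(p) formatC(floor(p * 1000 + 0.5) / 10, format = "f",
                                  digits = 1)

# Brute-force agreement tally, independent of the package internals: loops
# over rows and counts reference/test matches directly.
brute_agreement <- function(table, ref, test, polarity) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(table))) {
    r <- table[[ref]][i]; t <- table[[test]][i]
    keep <- switch(polarity,
                   PPA = r == "positive",
                   NPA = r == "negative",
                   OPA = TRUE)
    if (keep) {
      den <- den + 1L
      if (r == t) num <- num + 1L
    }
  }
  list(numerator = num, denominator = den, estimate = num / den)
}

# Brute-force zeta computation from the eight agreements.
brute_zetas <- function(table) {
  g <- function(ref, test, pol) brute_agreement(table, ref, test, pol)$estimate
  c(zeta_ppa1 = g("ccd1", "ccd2", "PPA") - g("ccd1", "fcd", "PPA"),
    zeta_ppa2 = g("ccd2", "ccd1", "PPA") - g("ccd2", "fcd", "PPA"),
    zeta_npa1 = g("ccd1", "ccd2", "NPA") - g("ccd1", "fcd", "NPA"),
    zeta_npa2 = g("ccd2", "ccd1", "NPA") - g("ccd2", "fcd", "NPA"))
}
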