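read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

guess_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a paired call table from TSV/CSV
#'
#' Expects header columns `sample_id`, `ccd1`, `ccd2`, `fcd` and optionally
#' `stratum`; call values POS/NEG/INVALID (case-insensitive, long spellings
#' accepted). Malformed rows are reported with their line numbers.
#'
#' @param path file path; tab-separated unless the extension is `.csv`.
#' @return A [paired_call_table].
#' @export
read_calls <- function(path) {
  df <- read_table_checked(path, c("sample_id", "ccd1", "ccd2", "fcd"),
                           sep = guess_sep(path))
  for (arm in c("ccd1", "ccd2", "fcd")) {
    x <- tolower(trimws(as.character(df[[arm]])))
    x[x %in% c("pos", "+")] <- "positive"
    x[x %in% c("neg", "-")] <- "negative"
    bad <- !(x %in% call_levels)
    if (any(bad))
      stop("unknown ", arm, " value '", df[[arm]][which(bad)[1]],
           "' at line ", which(bad)[1] + 1L, " of ", path, call. = FALSE)
  }
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  as_paired_call_table(df)
}

#' Read a dilution series from TSV/CSV
#'
#' Columns: `analyte`, `level`, `detected`, `replicates`.
#'
#' @param path file path.
#' @return A named list of [dilution_series], one per analyte.
#' @export
read_series <- function(path) {
  df <- read_table_checked(path, c("analyte", "level", "detected", "replicates"),
                           sep = guess_sep(path))
  out <- lapply(split(df, df$analyte), function(s) {
    s <- s[order(s$level), , drop = FALSE]
    dilution_series(s$level, s$detected, s$replicates, analyte = s$analyte[1])
  })
  out
}

#' Read LoH or copy-number segment tables
#'
#' BED-like tab-separated tables. For `kind = "cn"`: columns `chrom`,
#' `start`, `end`, `copy_state`. For `kind = "loh"`: columns `segment_id`,
#' `chrom`, `length_mb`, `loh` (plus any extras, preserved).
#'
#' @param path file path.
#' @param kind `"cn"` or `"loh"`.
#' @return A data.frame.
#' @export
read_segments <- function(path, kind = c("cn", "loh")) {
  kind <- match.arg(kind)
  required <- if (kind == "cn") c("chrom", "start", "end", "copy_state")
  else c("segment_id", "chrom", "length_mb", "loh")
  df <- read_table_checked(path, required, sep = guess_sep(path))
  if (kind == "loh") df$loh <- as.logical(df$loh)
  df
}

#' Read a precision panel from TSV/CSV
#'
#' Long-format replicate table with columns `operator`, `lot`, `run`,
#' `replicate`, `value` (an `instrument` column is accepted and preserved).
#'
#' @param path file path.
#' @return A data.frame suitable for [variance_components()].
#' @export
read_precision_panel <- function(path) {
  read_table_checked(path, c("operator", "lot", "run", "value"),
                     sep = guess_sep(path))
}

#' Read a variant table from CSV/TSV or minimal VCF
#'
#' The tabular format carries the [variant_table] columns directly. The VCF
#' route reads a minimal VCF v4.2 subset (via the vcfR package) with INFO
#' keys `VF` (variant frequency), `DP` (depth), `CSQ` (consequence class),
#' `GERM` (comma-separated germline flags or absent) and `GENE`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"table"` or `"vcf"`.
#' @return A [variant_table].
#' @export
read_variants <- function(path, format = c("auto", "table", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
  else "table"
  if (format == "table") {
    df <- read_table_checked(path, c("chrom", "pos", "ref", "alt", "vf",
                                     "depth", "consequence"),
                             sep = guess_sep(path))
    ge <- if ("germline_evidence" %in% names(df)) {
      x <- as.character(df$germline_evidence)
      replace(x, is.na(x) | x == ".", "")
    } else ""
    return(variant_table(df$chrom, df$pos, df$ref, df$alt, df$vf, df$depth,
                         df$consequence, germline_evidence = ge,
                         gene = df[["gene"]] %||% NA_character_))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else t(as.matrix(fix))
  info1 <- function(key) vcfR::extract.info(v, element = key)
  germ <- info1("GERM")
  germ <- ifelse(is.na(germ) | germ == ".", "", germ)
  variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
                fix[, "ALT"], as.numeric(info1("VF")),
                as.integer(info1("DP")), tolower(info1("CSQ")),
                germline_evidence = germ,
                gene = info1("GENE"))
}

#' Write a variant table as minimal VCF v4.2
#'
#' Writes plain-text VCF with 1-based positions and the INFO keys consumed
#' by [read_variants()] (`VF`, `DP`, `CSQ`, `GERM`, `GENE`). Round-trips to
#' an identical [variant_table].
#'
#' @param variants a [variant_table].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VF,Number=1,Type=Float,Description=\"Variant frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GERM,Number=.,Type=String,Description=\"Germline evidence flags\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("VF=%s;DP=%d;CSQ=%s%s%s",
                  formatC(variants$vf, format = "g", digits = 15),
                  variants$depth, variants$consequence,
                  ifelse(variants$germline_evidence == "", "",
                         paste0(";GERM=", variants$germline_evidence)),
                  ifelse(is.na(variants$gene), "",
                         paste0(";GENE=", variants$gene)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", variants$chrom,
                  variants$pos, variants$ref, variants$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Render an analysis result as JSON or a text table
#'
#' JSON output carries full numeric precision plus the seed, configuration,
#' configuration hash and assumption flags; the text table mirrors the
#' familiar CDx summary layout (biomarker, N, PPA and NPA with one-decimal
#' percentages).
#'
#' @param results a `cdx_concordance` fit, or a named list of them (one per
#'   biomarker) for the text table.
#' @param style `"json"` or `"text_table"`.
#' @param path optional output file; when omitted the document is returned.
#' @return A character scalar (JSON) or character vector of table lines,
#'   invisibly when written to `path`.
#' @export
render_report <- function(results, style = c("json", "text_table"),
                          path = NULL) {
  style <- match.arg(style)
  single <- inherits(results, "cdx_concordance")
  if (single) results <- list(result = results)
  if (style == "json") {
    doc <- lapply(results, concordance_as_list)
    if (single) doc <- doc[[1]]
    out <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
  } else {
    header <- sprintf("%-20s %6s %-24s %-24s", "biomarker", "N",
                      "PPA (95% CI)", "NPA (95% CI)")
    fmt <- function(e) sprintf("%s (%s, %s)", format_percent(e$estimate),
                               format_percent(e$ci_low),
                               format_percent(e$ci_high))
    rows <- vapply(names(results), function(nm) {
      x <- results[[nm]]
      sprintf("%-20s %6d %-24s %-24s", nm, x$n,
              fmt(x$agreements$ppa_c1f), fmt(x$agreements$npa_c1f))
    }, character(1))
    out <- c(header, rows)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

concordance_as_list <- function(x) {
  list(
    n = x$n,
    filter_summary = x$filter_summary,
    agreements = lapply(x$agreements, function(e)
      e[c("kind", "reference_arm", "test_arm", "numerator", "denominator",
          "estimate", "ci_low", "ci_high", "ci_method")]),
    zetas = lapply(unclass(x$zetas), function(z)
      z[c("point", "ci_low", "ci_high", "method")]),
    noninferiority = unclass(x$noninferiority),
    prevalence_adjusted = if (is.null(x$prevalence_adjusted)) NULL
    else unclass(x$prevalence_adjusted)[
      c("ppa_adjusted", "npa_adjusted", "population_prevalence",
        "sample_prevalence", "comparator")],
    config = x$config,
    config_hash = x$config_hash,
    seed = x$config$seed)
}
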