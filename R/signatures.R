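#' Microsatellite instability status from frameshift-mutated loci
#'
#' MSI-high is called when the number of microsatellite loci carrying
#' frameshift mutations reaches the threshold (default 39) out of the
#' examined locus universe (default 5,721 loci). An incomplete locus table
#' yields an indeterminate status unless the universe size is overridden.
#'
#' @param table data.frame with per-locus columns `locus_id` and
#'   `frameshift_mutated` (logical), or a single integer count of
#'   frameshift-mutated loci.
#' @param threshold_loci minimum mutated-locus count for MSI-high
#'   (default 39, inclusive).
#' @param n_loci expected locus universe (default 5721); when `table` is a
#'   data.frame its row count must equal this unless overridden.
#' @return `"MSI_high"`, `"MSS"` or `"indeterminate"`.
#' @export
call_msi <- function(table, threshold_loci = 39, n_loci = 5721) {
  if (is.data.frame(table)) {
    miss <- setdiff(c("locus_id", "frameshift_mutated"), names(table))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(table$locus_id))
      stop("duplicate locus_id", call. = FALSE)
    if (nrow(table) != n_loci) return("indeterminate")
    count <- sum(table$frameshift_mutated)
  } else {
    count <- as.integer(table)
    if (is.na(count) || count < 0 || count > n_loci)
      stop("frameshift locus count must lie in [0, n_loci]", call. = FALSE)
  }
  if (count >= threshold_loci) "MSI_high" else "MSS"
}

tmb_eligible_consequences <- c("missense", "nonsense", "inframe_indel",
                               "frameshift")
consequence_levels <- c(tmb_eligible_consequences, "synonymous", "splice",
                        "other")
germline_flags <- c("dbsnp151", "gnomad_ac_gt0", "curated_benign")

#' Construct a variant table
#'
#' Minimal small-variant records as consumed by the TMB computation: genomic
#' coordinates, alleles, variant frequency, depth, a coding-consequence
#' class, and pre-annotated germline-evidence flags (presence in dbSNP151,
#' gnomAD allele count > 0, or a curated benign list).
#'
#' @param chrom,pos,ref,alt variant coordinates (1-based) and alleles.
#' @param vf variant frequency in \[0, 1\].
#' @param depth read depth.
#' @param consequence one of missense, nonsense, inframe_indel, frameshift,
#'   synonymous, splice, other.
#' @param germline_evidence list of character vectors of flags per variant
#'   (subset of dbsnp151, gnomad_ac_gt0, curated_benign), or a single
#'   comma-separated character vector; empty means no germline evidence.
#' @param gene optional gene symbols.
#' @return A `data.frame` of class `variant_table` (germline flags stored as
#'   a comma-joined string, `""` when absent).
#' @export
variant_table <- function(chrom, pos, ref, alt, vf, depth, consequence,
                          germline_evidence = "", gene = NA_character_) {
  n <- length(pos)
  if (any(pos < 1)) stop("pos must be >= 1 (1-based)", call. = FALSE)
  if (any(vf < 0 | vf > 1)) stop("vf must lie in [0, 1]", call. = FALSE)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  vf <- rep_len(as.numeric(vf), n)
  depth <- rep_len(as.integer(depth), n)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  consequence <- rep_len(tolower(as.character(consequence)), n)
  bad <- !(consequence %in% consequence_levels)
  if (any(bad))
    stop("unknown consequence: ", paste(unique(consequence[bad]), collapse = ", "),
         call. = FALSE)
  if (is.list(germline_evidence))
    germline_evidence <- vapply(germline_evidence, paste, character(1),
                                collapse = ",")
  germline_evidence <- rep_len(as.character(germline_evidence), n)
  flags <- strsplit(germline_evidence, ",", fixed = TRUE)
  bad_flag <- unlist(flags)[!(unlist(flags) %in% c(germline_flags, ""))]
  if (length(bad_flag))
    stop("unknown germline flag: ", paste(unique(bad_flag), collapse = ", "),
         call. = FALSE)
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = ref, alt = alt, vf = as.numeric(vf),
                    depth = as.integer(depth), consequence = consequence,
                    germline_evidence = germline_evidence,
                    gene = rep_len(as.character(gene), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Tumor mutational burden
#'
#' Counts eligible somatic mutations — non-synonymous missense, nonsense,
#' in-frame insertion/deletion and frameshift variants with no germline
#' evidence (absent from dbSNP151, gnomAD AC>0, and the curated benign
#' list) — and divides by the sequenced footprint in megabases. TMB-high is
#' called at or above the cutoff (default 10 mutations/Mb, inclusive).
#'
#' @param variants a [variant_table].
#' @param panel_mb sequenced footprint in Mb (> 0). The footprint of the
#'   assay is not part of the variant table and must be supplied; 30 Mb is a
#'   conventional whole-exome footprint.
#' @param cutoff TMB-high cutoff in mutations/Mb (default 10).
#' @return A list with `tmb_value`, `tmb_class` (`"high"`/`"not_high"`) and
#'   `eligible_count`.
#' @export
compute_tmb <- function(variants, panel_mb = 30, cutoff = 10) {
  if (!is.numeric(panel_mb) || panel_mb <= 0)
    stop("invalid footprint: panel_mb must be > 0", call. = FALSE)
  eligible <- variants$consequence %in% tmb_eligible_consequences &
    (is.na(variants$germline_evidence) | variants$germline_evidence == "")
  eligible_count <- sum(eligible)
  tmb_value <- eligible_count / panel_mb
  list(tmb_value = tmb_value,
       tmb_class = if (tmb_value >= cutoff) "high" else "not_high",
       eligible_count = eligible_count)
}

#' Genomic loss-of-heterozygosity percentage and class
#'
#' Genomic LoH is the percentage of the 552 canonical 2-6 Mb chromosome
#' segments showing loss of heterozygosity. The class is Indeterminate when
#' the sample fails QC (at most `min_snps` heterozygous SNPs read, or sample
#' depth below `min_depth`); otherwise the percentage, rounded to the
#' nearest integer percent, is classified High (>= 16), Equivocal (11-15) or
#' Low (< 11).
#'
#' @param table data.frame with a logical `loh` column, one row per segment
#'   (552 expected), or a single integer count of LoH segments.
#' @param snps_read,sample_depth sample-level QC totals (required when
#'   `table` is a count; read from attributes or arguments otherwise).
#' @param n_segments segment universe size (default 552).
#' @param min_snps,min_depth QC thresholds (defaults 3000 SNPs, 200x).
#' @return A list with `loh_percent` and `loh_class`.
#' @export
call_genomic_loh <- function(table, snps_read, sample_depth,
                             n_segments = 552, min_snps = 3000,
                             min_depth = 200) {
  loh_count <- if (is.data.frame(table)) {
    if (!"loh" %in% names(table)) stop("missing 'loh' column", call. = FALSE)
    if (nrow(table) != n_segments)
      stop("expected ", n_segments, " segments, got ", nrow(table),
           call. = FALSE)
    sum(table$loh)
  } else as.integer(table)
  if (missing(snps_read) || missing(sample_depth))
    stop("incomplete input: sample totals snps_read and sample_depth required",
         call. = FALSE)
  loh_percent <- 100 * loh_count / n_segments
  cls <- if (snps_read <= min_snps || sample_depth < min_depth) "Indeterminate"
  else {
    pct <- round_half_up(loh_percent)
    if (pct >= 16) "High" else if (pct >= 11) "Equivocal" else "Low"
  }
  list(loh_percent = loh_percent, loh_class = cls)
}

round_half_up <- function(x, digits = 0) floor(x * 10^digits + 0.5) / 10^digits

#' Per-segment LoH from B-allele fractions
#'
#' Flags a segment as showing loss of heterozygosity when the mean
#' major-allele fraction of its heterozygous SNPs reaches the threshold
#' (default 0.75); balanced heterozygosity gives fractions near 0.5. This
#' per-segment rule is an implementation choice of this package and is kept
#' in its own function so precomputed segment calls can bypass it. Segments
#' whose SNP density falls below `min_snps_per_mb` are flagged
#' low-confidence; segments with no heterozygous SNPs are unevaluable (`NA`).
#'
#' @param bafs list of numeric vectors of heterozygous-SNP B-allele
#'   fractions, one vector per segment.
#' @param major_fraction_threshold LoH threshold on the mean major-allele
#'   fraction (default 0.75, inclusive).
#' @param segment_mb optional numeric segment lengths (Mb) for the density
#'   flag.
#' @param min_snps_per_mb density target (default 17 SNPs/Mb).
#' @return A data.frame with `loh` (logical, `NA` when unevaluable),
#'   `mean_major_fraction`, `n_snps` and `low_confidence`.
#' @export
segment_loh_from_baf <- function(bafs, major_fraction_threshold = 0.75,
                                 segment_mb = NULL, min_snps_per_mb = 17) {
  if (!is.list(bafs)) bafs <- list(bafs)
  mmf <- vapply(bafs, function(b) {
    if (length(b) == 0) return(NA_real_)
    if (any(b < 0 | b > 1)) stop("BAF values must lie in [0, 1]", call. = FALSE)
    mean(pmax(b, 1 - b))
  }, numeric(1))
  n_snps <- lengths(bafs)
  low_conf <- if (is.null(segment_mb)) rep(FALSE, length(bafs))
  else n_snps / segment_mb < min_snps_per_mb
  data.frame(loh = ifelse(is.na(mmf), NA, mmf >= major_fraction_threshold),
             mean_major_fraction = mmf, n_snps = n_snps,
             low_confidence = low_conf)
}

#' Count large-scale state transitions
#'
#' A large-scale state transition (LST) is the loss of a chromosomal segment
#' strictly larger than 10 Mb. Gain and copy-neutral segments never count,
#' and the count is invariant to segment ordering.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (half-open, in base pairs or Mb via `length_mb`), `copy_state`
#'   (loss/neutral/gain); a `length_mb` column takes precedence over
#'   coordinates (assumed base pairs otherwise).
#' @param min_mb minimum loss length in Mb, exclusive (default 10).
#' @return Integer LST count.
#' @export
count_lst <- function(segments, min_mb = 10) {
  if (!all(c("chrom", "copy_state") %in% names(segments)))
    stop("segments need chrom and copy_state columns", call. = FALSE)
  state <- tolower(as.character(segments$copy_state))
  bad <- !(state %in% c("loss", "neutral", "gain"))
  if (any(bad))
    stop("unknown copy_state: ", paste(unique(state[bad]), collapse = ", "),
         call. = FALSE)
  len_mb <- if ("length_mb" %in% names(segments)) segments$length_mb
  else (segments$end - segments$start) / 1e6
  if (any(len_mb <= 0)) stop("segment lengths must be positive", call. = FALSE)
  loss <- state == "loss"
  # overlapping loss segments on one chromosome indicate malformed input
  if (all(c("start", "end") %in% names(segments)) && any(loss)) {
    for (ch in unique(segments$chrom[loss])) {
      s <- segments[loss & segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping loss segments on ", ch, call. = FALSE)
    }
  }
  sum(loss & len_mb > min_mb)
}

#' Genomic scar score
#'
#' Combines LoH-segment and LST evidence into a single score. The published
#' signature states only that LoH and LST contribute; the combination used
#' here — LoH segments scaled to a 0-100 percentage of the 552-segment
#' universe plus one point per LST — is an assumed default, is flagged as
#' such in the result, and both weights are configurable.
#'
#' @param loh_segment_count number of LoH segments (>= 0).
#' @param lst_count number of large-scale state transitions (>= 0).
#' @param w_loh weight per LoH segment (default 100/552, i.e. the LoH
#'   percentage scale).
#' @param w_lst weight per LST (default 1).
#' @return A list with `gss` and `formula_assumed = TRUE`.
#' @export
compute_gss <- function(loh_segment_count, lst_count, w_loh = 100 / 552,
                        w_lst = 1) {
  if (w_loh < 0 || w_lst < 0) stop("negative weights rejected", call. = FALSE)
  if (loh_segment_count < 0 || lst_count < 0)
    stop("counts must be >= 0", call. = FALSE)
  list(gss = w_loh * loh_segment_count + w_lst * lst_count,
       formula_assumed = TRUE)
}

#' Homologous recombination deficiency call
#'
#' HRD is positive when the sample carries a pathogenic BRCA1/BRCA2 mutation
#' or its genomic scar score reaches the cutoff (GSS >= 46, inclusive);
#' otherwise negative.
#'
#' @param gss genomic scar score (may be `NA` if `brca_status` is known).
#' @param brca_status `"pathogenic"`, `"wild_type"` or `"unknown"`.
#' @param gss_cutoff default 46.
#' @return `"positive"` or `"negative"`.
#' @export
call_hrd <- function(gss, brca_status = c("unknown", "pathogenic", "wild_type"),
                     gss_cutoff = 46) {
  brca_status <- match.arg(brca_status)
  if ((is.null(gss) || is.na(gss)) && brca_status == "unknown")
    stop("indeterminate: GSS missing and BRCA status unknown", call. = FALSE)
  if (brca_status == "pathogenic") return("positive")
  if (!is.null(gss) && !is.na(gss) && gss >= gss_cutoff) "positive"
  else "negative"
}

#' Copy-number amplification classification
#'
#' Classifies an estimated gene copy number against the caller's
#' amplification threshold, reporting `below_lod` when the threshold is met
#' only below the validated reliable-detection bound (default 8.3 copies,
#' the lowest copy level with >= 95% detection).
#'
#' @param copies estimated copy number (>= 0).
#' @param amp_threshold caller amplification threshold (default 8.3 copies,
#'   inclusive).
#' @param lod_copies reliable-detection bound in copies (default 8.3).
#' @return `"amplified"`, `"not_amplified"` or `"below_lod"`.
#' @export
classify_cna <- function(copies, amp_threshold = 8.3, lod_copies = 8.3) {
  if (!is.numeric(copies) || copies < 0)
    stop("copies must be >= 0", call. = FALSE)
  if (copies < amp_threshold) "not_amplified"
  else if (copies < lod_copies) "below_lod"
  else "amplified"
}

#' Call all genomic signatures for one sample
#'
#' Convenience wrapper running the MSI, TMB, genomic LoH, LST, GSS and HRD
#' callers on one sample's tables and collecting a single result record.
#'
#' @param variants a [variant_table].
#' @param msi_table MSI locus table (see [call_msi()]).
#' @param loh_table LoH segment table with a logical `loh` column.
#' @param cn_segments copy-number segment table (see [count_lst()]).
#' @param snps_read,sample_depth LoH QC totals.
#' @param brca_status BRCA1/2 mutation status.
#' @param panel_mb,tmb_cutoff,msi_threshold,gss_cutoff caller thresholds.
#' @return An object of class `signature_result`.
#' @export
call_signatures <- function(variants, msi_table, loh_table, cn_segments,
                            snps_read, sample_depth,
                            brca_status = "unknown", panel_mb = 30,
                            tmb_cutoff = 10, msi_threshold = 39,
                            gss_cutoff = 46) {
  msi <- call_msi(msi_table, threshold_loci = msi_threshold)
  tmb <- compute_tmb(variants, panel_mb = panel_mb, cutoff = tmb_cutoff)
  loh <- call_genomic_loh(loh_table, snps_read = snps_read,
                          sample_depth = sample_depth)
  lst <- count_lst(cn_segments)
  loh_count <- if (is.data.frame(loh_table)) sum(loh_table$loh)
  else as.integer(loh_table)
  gss <- compute_gss(loh_count, lst)
  hrd <- call_hrd(gss$gss, brca_status, gss_cutoff = gss_cutoff)
  structure(list(msi_status = msi, tmb_value = tmb$tmb_value,
                 tmb_class = tmb$tmb_class,
                 eligible_mutations = tmb$eligible_count,
                 loh_percent = loh$loh_percent, loh_class = loh$loh_class,
                 lst_count = lst, gss = gss$gss,
                 gss_formula_assumed = gss$formula_assumed,
                 hrd_call = hrd, brca_status = brca_status),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("genomic signature calls:\n")
  cat(sprintf("  MSI: %s\n  TMB: %.2f mut/Mb (%s, %d eligible)\n",
              x$msi_status, x$tmb_value, x$tmb_class, x$eligible_mutations))
  cat(sprintf("  genomic LoH: %.1f%% (%s)\n  LST: %d\n  GSS: %.1f%s\n",
              x$loh_percent, x$loh_class, x$lst_count, x$gss,
              if (x$gss_formula_assumed) " (assumed combination)" else ""))
  cat(sprintf("  HRD: %s (BRCA %s)\n", x$hrd_call, x$brca_status))
  invisible(x)
}
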