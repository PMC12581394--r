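#' Specification of a simulated concordance cohort
#'
#' Parameters of the latent-truth enrollment model used to emulate a
#' comparator-anchored concordance study: samples carry an unobserved
#' biomarker truth at prevalence `prevalence`; a noisy pre-test marker
#' (sensitivity/specificity `pretest_se`/`pretest_sp`) defines the
#' enrollment strata, and the cohort is enriched to a target fraction of
#' pre-test positives; the two comparator replicates share sensitivity
#' `ccd_se` and specificity `ccd_sp` with a tunable error dependence, and
#' the follow-on test has its own `fcd_se`/`fcd_sp` with errors drawn
#' independently of the comparator; invalid results are injected per arm.
#'
#' The replicate dependence is a shared-error mixture: with probability
#' `ccd_dependence` both comparator replicates reuse one error draw, with
#' the complement they err independently, so `ccd_dependence` is the
#' correlation between the two replicate error indicators.
#'
#' @param n_samples cohort size.
#' @param prevalence biomarker prevalence in the population.
#' @param ccd_se,ccd_sp comparator sensitivity and specificity (shared by
#'   the two replicates).
#' @param fcd_se,fcd_sp follow-on test sensitivity and specificity.
#' @param ccd_dependence correlation of the comparator replicate errors in
#'   \[0, 1\].
#' @param pretest_se,pretest_sp accuracy of the enrollment pre-test marker
#'   relative to truth.
#' @param invalid_rate probability that any single call is invalid
#'   (independent per arm and sample).
#' @param enrichment target fraction of pre-test-positive samples, or `NULL`
#'   for an unenriched cohort (strata then recorded as observed).
#' @param seed integer seed.
#' @return A list of class `concordance_sim_spec`.
#' @export
concordance_sim_spec <- function(n_samples = 500, prevalence = 0.3,
                                 ccd_se = 0.95, ccd_sp = 0.97,
                                 fcd_se = 0.95, fcd_sp = 0.97,
                                 ccd_dependence = 0.3,
                                 pretest_se = 0.9, pretest_sp = 0.9,
                                 invalid_rate = 0, enrichment = NULL,
                                 seed = NULL) {
  probs <- c(prevalence = prevalence, ccd_se = ccd_se, ccd_sp = ccd_sp,
             fcd_se = fcd_se, fcd_sp = fcd_sp,
             ccd_dependence = ccd_dependence, pretest_se = pretest_se,
             pretest_sp = pretest_sp, invalid_rate = invalid_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.null(enrichment) && (enrichment <= 0 || enrichment >= 1))
    stop("enrichment fraction must lie in (0, 1)", call. = FALSE)
  structure(c(as.list(probs), list(n_samples = as.integer(n_samples),
                                   enrichment = enrichment, seed = seed)),
            class = "concordance_sim_spec")
}

#' Simulate a comparator-anchored concordance cohort
#'
#' Draws a [paired_call_table] from a [concordance_sim_spec], retaining the
#' latent truth for oracle checks. With enrichment, sample truths are drawn
#' conditional on the pre-test stratum via Bayes' rule so the cohort hits
#' the target fraction of pre-test positives exactly (up to rounding).
#'
#' @param spec a [concordance_sim_spec].
#' @return A `paired_call_table` with attributes `truth` (logical vector)
#'   and `spec`.
#' @export
simulate_concordance_cohort <- function(spec) {
  stopifnot(inherits(spec, "concordance_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    pi <- spec$prevalence
    if (is.null(spec$enrichment)) {
      truth <- stats::runif(n) < pi
      pretest <- ifelse(truth, stats::runif(n) < spec$pretest_se,
                        stats::runif(n) >= spec$pretest_sp)
      stratum <- rep("unenriched", n)
    } else {
      # P(truth | pretest stratum) by Bayes' rule from the population model
      p_pre_pos <- spec$pretest_se * pi + (1 - spec$pretest_sp) * (1 - pi)
      p_truth_given_pos <- spec$pretest_se * pi / p_pre_pos
      p_truth_given_neg <- (1 - spec$pretest_se) * pi / (1 - p_pre_pos)
      n_pos <- round(n * spec$enrichment)
      pretest <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
      truth <- stats::runif(n) <
        ifelse(pretest, p_truth_given_pos, p_truth_given_neg)
      stratum <- ifelse(pretest, "pretest_positive", "pretest_negative")
    }
    # an error flips the true state, so the call is positive iff truth XOR err
    call_arm <- function(truth, err) ifelse(xor(truth, err), "positive",
                                            "negative")
    err_prob <- function(truth, se, sp) ifelse(truth, 1 - se, 1 - sp)
    # shared-error mixture between the two comparator replicates
    shared <- stats::runif(n) < spec$ccd_dependence
    e_common <- stats::runif(n) < err_prob(truth, spec$ccd_se, spec$ccd_sp)
    e1_ind <- stats::runif(n) < err_prob(truth, spec$ccd_se, spec$ccd_sp)
    e2_ind <- stats::runif(n) < err_prob(truth, spec$ccd_se, spec$ccd_sp)
    err1 <- ifelse(shared, e_common, e1_ind)
    err2 <- ifelse(shared, e_common, e2_ind)
    errf <- stats::runif(n) < err_prob(truth, spec$fcd_se, spec$fcd_sp)
    ccd1 <- call_arm(truth, err1)
    ccd2 <- call_arm(truth, err2)
    fcd <- call_arm(truth, errf)
    if (spec$invalid_rate > 0) {
      for (arm in c("ccd1", "ccd2", "fcd")) {
        inv <- stats::runif(n) < spec$invalid_rate
        assign(arm, replace(get(arm), inv, "invalid"))
      }
    }
    out <- paired_call_table(sprintf("S%05d", seq_len(n)), ccd1, ccd2, fcd,
                             stratum = stratum)
    attr(out, "truth") <- truth
    attr(out, "pretest") <- pretest
    attr(out, "spec") <- spec
    out
  })
}

#' Population zeta values implied by a cohort simulation spec
#'
#' Closed-form (total-probability) values of the four agreement differences
#' under a [concordance_sim_spec], used as the simulation truth in coverage
#' studies. Conditional proportions are the ratios of expected cell
#' probabilities in the population the cohort is drawn from (the enriched
#' population when `enrichment` is set).
#'
#' @param spec a [concordance_sim_spec].
#' @return Named numeric vector of the four zetas.
#' @export
expected_zetas <- function(spec) {
  stopifnot(inherits(spec, "concordance_sim_spec"))
  pi <- if (is.null(spec$enrichment)) spec$prevalence else {
    p_pre_pos <- spec$pretest_se * spec$prevalence +
      (1 - spec$pretest_sp) * (1 - spec$prevalence)
    p_tp <- spec$pretest_se * spec$prevalence / p_pre_pos
    p_tn <- (1 - spec$pretest_se) * spec$prevalence / (1 - p_pre_pos)
    spec$enrichment * p_tp + (1 - spec$enrichment) * p_tn
  }
  rho <- spec$ccd_dependence
  # per-truth-state probabilities of a positive call
  p_pos <- function(se, sp, t) if (t) se else 1 - sp
  # joint P(ccd1 = +, ccd2 = +) given truth t under the shared-error mixture
  joint_cc_pos <- function(t) {
    p <- p_pos(spec$ccd_se, spec$ccd_sp, t)
    rho * p + (1 - rho) * p^2
  }
  joint_cc_neg <- function(t) {
    q <- 1 - p_pos(spec$ccd_se, spec$ccd_sp, t)
    rho * q + (1 - rho) * q^2
  }
  cell <- function(f) sum(vapply(c(TRUE, FALSE), function(t)
    f(t) * (if (t) pi else 1 - pi), numeric(1)))
  p_c1_pos <- cell(function(t) p_pos(spec$ccd_se, spec$ccd_sp, t))
  p_c1c2_pos <- cell(joint_cc_pos)
  p_c1f_pos <- cell(function(t) p_pos(spec$ccd_se, spec$ccd_sp, t) *
                      p_pos(spec$fcd_se, spec$fcd_sp, t))
  p_c1_neg <- 1 - p_c1_pos
  p_c1c2_neg <- cell(joint_cc_neg)
  p_c1f_neg <- cell(function(t) (1 - p_pos(spec$ccd_se, spec$ccd_sp, t)) *
                      (1 - p_pos(spec$fcd_se, spec$fcd_sp, t)))
  zp <- p_c1c2_pos / p_c1_pos - p_c1f_pos / p_c1_pos
  zn <- p_c1c2_neg / p_c1_neg - p_c1f_neg / p_c1_neg
  # the two replicates are exchangeable, so the C2-anchored zetas coincide
  c(zeta_ppa1 = zp, zeta_ppa2 = zp, zeta_npa1 = zn, zeta_npa2 = zn)
}

#' Simulate a dilution series from a logistic detection model
#'
#' Per-replicate detection is Bernoulli with probability
#' `plogis(slope * (log(level) - log(location)))`, where the location is
#' placed so that the detection probability equals 95% exactly at
#' `true_lod_level`; the true 95%-detection quantile of the model is
#' therefore `true_lod_level` by construction.
#'
#' @param true_lod_level level at which detection probability is 0.95.
#' @param slope positive logistic slope on the log-level scale.
#' @param levels increasing vector of tested levels (> 0).
#' @param replicates replicates per level (default 20).
#' @param seed integer seed.
#' @return A [dilution_series] with attribute `true_lod`.
#' @export
simulate_dilution_series <- function(true_lod_level, slope, levels,
                                     replicates = 20, seed = NULL) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  # logistic location such that p(true_lod_level) = 0.95
  loc <- log(true_lod_level) - stats::qlogis(0.95) / slope
  p <- stats::plogis(slope * (log(levels) - loc))
  detected <- with_seed(seed, stats::rbinom(length(levels), replicates, p))
  out <- dilution_series(levels, detected, replicates)
  attr(out, "true_lod") <- true_lod_level
  attr(out, "detection_prob") <- p
  out
}

#' Simulate a precision panel with additive random effects
#'
#' Generates replicate quantitative values for one panel member under the
#' crossed/nested precision design: operator/instrument crossed with
#' reagent lot, runs nested within each operator-by-lot cell, replicates
#' within runs. Values are the panel mean plus independent Gaussian random
#' effects per factor level and a residual per replicate. The default
#' design (3 operators x 3 lots, 2 runs per cell, 2 replicates per run)
#' yields the 36 replicates per panel member of a full within-lab study.
#'
#' @param mean panel-member mean value.
#' @param sigma_operator,sigma_lot,sigma_run,sigma_resid random-effect
#'   standard deviations (>= 0).
#' @param n_operators,n_lots,runs_per_cell,reps_per_run design sizes.
#' @param seed integer seed.
#' @return A data.frame with columns `operator`, `lot`, `run`, `replicate`,
#'   `value` (and an `instrument` column mirroring `operator`, since
#'   operator teams and instrument sets are confounded in this design).
#' @export
simulate_precision_panel <- function(mean = 10, sigma_operator = 0,
                                     sigma_lot = 0, sigma_run = 0,
                                     sigma_resid = 1,
                                     n_operators = 3, n_lots = 3,
                                     runs_per_cell = 2, reps_per_run = 2,
                                     seed = NULL) {
  sds <- c(sigma_operator, sigma_lot, sigma_run, sigma_resid)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  with_seed(seed, {
    design <- expand.grid(replicate = seq_len(reps_per_run),
                          run = seq_len(runs_per_cell),
                          lot = seq_len(n_lots),
                          operator = seq_len(n_operators))
    a_op <- stats::rnorm(n_operators, 0, sigma_operator)
    a_lot <- stats::rnorm(n_lots, 0, sigma_lot)
    cell_run <- interaction(design$operator, design$lot, design$run)
    a_run <- stats::rnorm(nlevels(cell_run), 0, sigma_run)
    value <- mean + a_op[design$operator] + a_lot[design$lot] +
      a_run[as.integer(cell_run)] +
      stats::rnorm(nrow(design), 0, sigma_resid)
    data.frame(operator = paste0("OP", design$operator),
               instrument = paste0("INST", design$operator),
               lot = paste0("LOT", design$lot),
               run = paste0("D", design$run),
               replicate = design$replicate, value = value,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a simulated signature sample
#'
#' Counts and attributes from which one sample's signature input tables are
#' generated with fully known truth.
#'
#' @param msi_frameshift_count frameshift-mutated MSI loci (<= `n_loci`).
#' @param eligible_mutation_count somatic TMB-eligible mutations.
#' @param germline_flagged_count additional variants carrying germline
#'   evidence (never TMB-eligible).
#' @param synonymous_count additional synonymous variants (never eligible).
#' @param panel_mb sequenced footprint in Mb.
#' @param loh_segment_count LoH-positive segments (<= `n_segments`).
#' @param lst_loss_lengths_mb lengths (Mb) of simulated loss segments; those
#'   strictly over 10 Mb are the true LSTs.
#' @param brca_status BRCA1/2 status for the HRD rule.
#' @param snps_read,sample_depth LoH QC totals.
#' @param n_loci,n_segments universe sizes (5721 loci, 552 segments).
#' @param seed integer seed.
#' @return A list of class `signature_sim_spec`.
#' @export
signature_sim_spec <- function(msi_frameshift_count = 0,
                               eligible_mutation_count = 0,
                               germline_flagged_count = 0,
                               synonymous_count = 0,
                               panel_mb = 30,
                               loh_segment_count = 0,
                               lst_loss_lengths_mb = numeric(0),
                               brca_status = "wild_type",
                               snps_read = 250000, sample_depth = 500,
                               n_loci = 5721, n_segments = 552,
                               seed = NULL) {
  if (msi_frameshift_count < 0 || msi_frameshift_count > n_loci)
    stop("msi_frameshift_count must lie in [0, n_loci]", call. = FALSE)
  if (loh_segment_count < 0 || loh_segment_count > n_segments)
    stop("loh_segment_count must lie in [0, n_segments]", call. = FALSE)
  if (eligible_mutation_count < 0 || germline_flagged_count < 0 ||
      synonymous_count < 0)
    stop("variant counts must be >= 0", call. = FALSE)
  if (any(lst_loss_lengths_mb <= 0))
    stop("loss segment lengths must be positive", call. = FALSE)
  structure(list(msi_frameshift_count = as.integer(msi_frameshift_count),
                 eligible_mutation_count = as.integer(eligible_mutation_count),
                 germline_flagged_count = as.integer(germline_flagged_count),
                 synonymous_count = as.integer(synonymous_count),
                 panel_mb = panel_mb,
                 loh_segment_count = as.integer(loh_segment_count),
                 lst_loss_lengths_mb = lst_loss_lengths_mb,
                 brca_status = brca_status, snps_read = snps_read,
                 sample_depth = sample_depth, n_loci = as.integer(n_loci),
                 n_segments = as.integer(n_segments), seed = seed),
            class = "signature_sim_spec")
}

#' Simulate signature input tables with known truth
#'
#' Emits a variant table, MSI locus table, LoH segment table and
#' copy-number segment table whose deterministic signature calls equal the
#' classes implied by `spec`; the implied truth is attached for oracle
#' checks.
#'
#' @param spec a [signature_sim_spec].
#' @return A list with `variants`, `msi_table`, `loh_table`, `cn_segments`,
#'   `snps_read`, `sample_depth`, `brca_status`, `panel_mb` and `truth`.
#' @export
simulate_signature_sample <- function(spec) {
  stopifnot(inherits(spec, "signature_sim_spec"))
  with_seed(spec$seed, {
    n_var <- spec$eligible_mutation_count + spec$germline_flagged_count +
      spec$synonymous_count
    eligible_cons <- sample(tmb_eligible_consequences,
                            spec$eligible_mutation_count, replace = TRUE)
    germ_cons <- sample(tmb_eligible_consequences,
                        spec$germline_flagged_count, replace = TRUE)
    germ_flags <- sample(germline_flags, spec$germline_flagged_count,
                         replace = TRUE)
    variants <- if (n_var > 0) {
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_var, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      variant_table(
        chrom = paste0("chr", sample(1:22, n_var, replace = TRUE)),
        pos = sample.int(2e8, n_var),
        ref = ref, alt = alt,
        vf = stats::runif(n_var, 0.05, 0.6),
        depth = sample(200:800, n_var, replace = TRUE),
        consequence = c(eligible_cons, germ_cons,
                        rep("synonymous", spec$synonymous_count)),
        germline_evidence = c(rep("", spec$eligible_mutation_count),
                              germ_flags, rep("", spec$synonymous_count)),
        gene = paste0("GENE", sample.int(500, n_var, replace = TRUE)))
    } else variant_table(character(0), integer(0), character(0), character(0),
                         numeric(0), integer(0), character(0), character(0))
    msi_table <- data.frame(
      locus_id = sprintf("MSI%04d", seq_len(spec$n_loci)),
      frameshift_mutated = seq_len(spec$n_loci) %in%
        sample.int(spec$n_loci, spec$msi_frameshift_count))
    loh_idx <- sample.int(spec$n_segments, spec$loh_segment_count)
    seg_len_mb <- stats::runif(spec$n_segments, 2, 6)
    loh_table <- data.frame(
      segment_id = seq_len(spec$n_segments),
      chrom = paste0("chr", rep_len(1:22, spec$n_segments)),
      length_mb = seg_len_mb,
      het_snp_count = pmax(stats::rpois(spec$n_segments, 17 * seg_len_mb), 1),
      loh = seq_len(spec$n_segments) %in% loh_idx)
    n_loss <- length(spec$lst_loss_lengths_mb)
    n_gain <- 2
    cn_segments <- data.frame(
      chrom = paste0("chr", seq_len(n_loss + n_gain)),
      start = 1e6, # one segment per chromosome; no overlap by construction
      end = 1e6 + c(spec$lst_loss_lengths_mb, c(1.5, 30)) * 1e6,
      copy_state = c(rep("loss", n_loss), rep("gain", n_gain)))
    true_lst <- sum(spec$lst_loss_lengths_mb > 10)
    true_tmb <- spec$eligible_mutation_count / spec$panel_mb
    true_loh_pct <- 100 * spec$loh_segment_count / spec$n_segments
    true_gss <- compute_gss(spec$loh_segment_count, true_lst)$gss
    truth <- list(
      msi_status = if (spec$msi_frameshift_count >= 39) "MSI_high" else "MSS",
      tmb_value = true_tmb,
      tmb_class = if (true_tmb >= 10) "high" else "not_high",
      loh_percent = true_loh_pct,
      loh_class = if (spec$snps_read <= 3000 || spec$sample_depth < 200)
        "Indeterminate"
      else if (round_half_up(true_loh_pct) >= 16) "High"
      else if (round_half_up(true_loh_pct) >= 11) "Equivocal" else "Low",
      lst_count = true_lst, gss = true_gss,
      hrd_call = if (identical(spec$brca_status, "pathogenic") ||
                     true_gss >= 46) "positive" else "negative")
    list(variants = variants, msi_table = msi_table, loh_table = loh_table,
         cn_segments = cn_segments, snps_read = spec$snps_read,
         sample_depth = spec$sample_depth, brca_status = spec$brca_status,
         panel_mb = spec$panel_mb, truth = truth, spec = spec)
  })
}
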