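test_that("MSI threshold is 39 mutated loci, inclusive and monotone", {
  expect_equal(call_msi(39), "MSI_high")
  expect_equal(call_msi(38), "MSS")
  expect_equal(call_msi(0), "MSS")
  # monotone: adding a mutated locus never flips high -> stable
  statuses <- vapply(0:100, call_msi, character(1))
  first_high <- match("MSI_high", statuses)
  expect_true(all(statuses[first_high:length(statuses)] == "MSI_high"))
  # incomplete locus universe is indeterminate
  short <- data.frame(locus_id = 1:100, frameshift_mutated = TRUE)
  expect_equal(call_msi(short), "indeterminate")
  expect_equal(call_msi(short, n_loci = 100), "MSI_high")
})

test_that("TMB counts eligible somatic mutations per megabase", {
  mk <- function(consequence, germ = "") {
    n <- length(consequence)
    variant_table(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
                  vf = 0.3, depth = 300, consequence = consequence,
                  germline_evidence = rep_len(germ, n))
  }
  # hand-enumerated fixture: 4 missense + 2 nonsense somatic are eligible;
  # germline-flagged and synonymous variants are not
  fix <- rbind(mk(rep("missense", 4)), mk(rep("nonsense", 2)),
               mk(rep("missense", 3), germ = "gnomad_ac_gt0"),
               mk(rep("synonymous", 2)),
               mk("frameshift", germ = "dbsnp151"))
  res <- compute_tmb(fix, panel_mb = 30)
  expect_equal(res$eligible_count, 6)
  expect_equal(res$tmb_value, 6 / 30)
  # boundary: 300 eligible over 30 Mb is exactly 10 mut/Mb and high
  big <- mk(rep("missense", 300))
  expect_equal(compute_tmb(big, panel_mb = 30)$tmb_class, "high")
  expect_equal(compute_tmb(mk(rep("missense", 299)),
                           panel_mb = 30)$tmb_class, "not_high")
  empty <- mk(character(0))
  expect_equal(compute_tmb(empty, 30)$tmb_value, 0)
  expect_error(compute_tmb(fix, panel_mb = 0), "footprint")
})

test_that("adding germline-flagged variants never changes TMB", {
  base <- variant_table("chr1", 1:5, "A", "G", 0.2, 250, "missense")
  extra <- variant_table("chr2", 1:3, "C", "T", 0.2, 250, "nonsense",
                         germline_evidence = "dbsnp151,gnomad_ac_gt0")
  expect_equal(compute_tmb(rbind(base, extra), 30)$tmb_value,
               compute_tmb(base, 30)$tmb_value)
  # one extra eligible variant adds exactly 1/panel_mb
  plus <- variant_table("chr3", 7, "G", "A", 0.2, 250, "frameshift")
  expect_equal(compute_tmb(rbind(base, plus), 30)$tmb_value -
                 compute_tmb(base, 30)$tmb_value, 1 / 30)
})

test_that("genomic LoH classes follow the published cutpoints", {
  loh <- call_genomic_loh(89, snps_read = 250000, sample_depth = 500)
  expect_equal(loh$loh_percent, 100 * 89 / 552, tolerance = 1e-12) # 16.1%
  expect_equal(loh$loh_class, "High")
  expect_equal(call_genomic_loh(0, 250000, 500)$loh_class, "Low")
  # QC failures dominate any segment pattern
  expect_equal(call_genomic_loh(89, 2900, 500)$loh_class, "Indeterminate")
  expect_equal(call_genomic_loh(89, 3000, 500)$loh_class, "Indeterminate")
  expect_equal(call_genomic_loh(89, 250000, 199)$loh_class, "Indeterminate")
  # classes partition the count range under determinate QC
  classes <- vapply(0:552, function(k)
    call_genomic_loh(k, 250000, 500)$loh_class, character(1))
  expect_true(all(classes %in% c("High", "Equivocal", "Low")))
  expect_true(!is.unsorted(match(classes, c("Low", "Equivocal", "High"))))
})

test_that("segment LoH from BAFs applies the mean major-fraction threshold", {
  res <- segment_loh_from_baf(list(rep(0.5, 10), rep(0.95, 10),
                                   c(0.7, 0.7, 0.6, 0.6, 0.82, 0.82, 0.95)))
  expect_false(res$loh[1])
  expect_true(res$loh[2])
  # boundary: mean major fraction 0.749 vs threshold 0.75 is not LoH
  just_below <- segment_loh_from_baf(list(c(0.749)))
  expect_false(just_below$loh[1])
  at <- segment_loh_from_baf(list(c(0.75)))
  expect_true(at$loh[1])
  # no SNPs: unevaluable; sparse segment flagged low-confidence
  mixed <- segment_loh_from_baf(list(numeric(0), rep(0.9, 5)),
                                segment_mb = c(3, 3))
  expect_true(is.na(mixed$loh[1]))
  expect_true(mixed$low_confidence[2]) # 5 SNPs over 3 Mb < 17/Mb
})

test_that("LST counts losses strictly longer than 10 Mb, order-invariant", {
  seg <- data.frame(chrom = c("chr1", "chr2", "chr3", "chr4", "chr5"),
                    start = 0,
                    end = c(8, 11, 25, 40, 12) * 1e6,
                    copy_state = c("loss", "loss", "loss", "gain", "neutral"))
  expect_equal(count_lst(seg), 2)
  expect_equal(count_lst(seg[sample(5), ]), 2)
  exact10 <- data.frame(chrom = "chr1", start = 0, end = 10e6,
                        copy_state = "loss")
  expect_equal(count_lst(exact10), 0)
  twelve <- data.frame(chrom = "chr1", start = 0, end = 12e6,
                       copy_state = "loss")
  expect_equal(count_lst(twelve), 1)
  overlap <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(12e6, 20e6),
                        copy_state = "loss")
  expect_error(count_lst(overlap), "overlapping")
})

test_that("GSS is monotone in both inputs and zero at the origin", {
  expect_equal(compute_gss(0, 0)$gss, 0)
  expect_true(compute_gss(150, 21)$gss > compute_gss(150, 20)$gss)
  expect_true(compute_gss(151, 20)$gss > compute_gss(150, 20)$gss)
  expect_true(compute_gss(10, 5)$formula_assumed)
  expect_error(compute_gss(10, 5, w_loh = -1), "negative")
  expect_error(compute_gss(-1, 5), ">= 0")
})

test_that("HRD follows the disjunctive BRCA-or-GSS rule", {
  expect_equal(call_hrd(20, "pathogenic"), "positive")
  expect_equal(call_hrd(46, "wild_type"), "positive") # boundary inclusive
  expect_equal(call_hrd(45, "wild_type"), "negative")
  expect_equal(call_hrd(50, "unknown"), "positive")
  expect_error(call_hrd(NA, "unknown"), "indeterminate")
})

test_that("CNA classification respects the copies LoD bound", {
  expect_equal(classify_cna(8.3), "amplified") # boundary inclusive
  expect_equal(classify_cna(2), "not_amplified")
  expect_equal(classify_cna(6), "not_amplified")
  # threshold met but below the reliable-detection bound
  expect_equal(classify_cna(7, amp_threshold = 6), "below_lod")
  expect_error(classify_cna(-1), ">= 0")
})

test_that("signature callers recover simulated truth end-to-end", {
  specs <- list(
    signature_sim_spec(msi_frameshift_count = 39,
                       eligible_mutation_count = 310,
                       germline_flagged_count = 40, synonymous_count = 25,
                       loh_segment_count = 95,
                       lst_loss_lengths_mb = c(12, 11, 9),
                       brca_status = "wild_type", seed = 301),
    signature_sim_spec(msi_frameshift_count = 5,
                       eligible_mutation_count = 150,
                       loh_segment_count = 30,
                       lst_loss_lengths_mb = c(15, 20, 30, 11, 8),
                       brca_status = "pathogenic", seed = 302),
    signature_sim_spec(msi_frameshift_count = 0,
                       eligible_mutation_count = 10,
                       loh_segment_count = 0, snps_read = 2000, seed = 303))
  for (spec in specs) {
    s <- simulate_signature_sample(spec)
    res <- call_signatures(s$variants, s$msi_table, s$loh_table,
                           s$cn_segments, s$snps_read, s$sample_depth,
                           s$brca_status, panel_mb = s$panel_mb)
    for (field in names(s$truth))
      expect_equal(res[[field]], s$truth[[field]], info = field)
  }
  # spec example: eligible 150 over 30 Mb is TMB 5, not high
  expect_equal(simulate_signature_sample(
    signature_sim_spec(eligible_mutation_count = 150, seed = 1))$truth$tmb_value, 5)
  expect_error(signature_sim_spec(msi_frameshift_count = 6000),
               "n_loci")
  expect_error(signature_sim_spec(loh_segment_count = 600), "n_segments")
})
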