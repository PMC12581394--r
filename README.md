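# cdxval

Statistics for validating a follow-on companion diagnostic (CDx) against an
approved comparator, and for the analytical validation of a sequencing-based
tumor-profiling assay.

## The problem

A new tumor test seeking companion-diagnostic status usually cannot be
compared to a gold standard — only to an approved comparator test that is
itself imperfect. The accepted study design tests each sample twice with the
comparator CDx (CCD1, CCD2) and once with the follow-on CDx (FCD), and asks
whether the new test agrees with a comparator replicate as well as the
comparator agrees with itself. cdxval implements:

* **Concordance statistics** — positive/negative percent agreement (PPA/NPA)
  with Wilson, Clopper-Pearson and continuity-corrected Wilson intervals;
  the four agreement differences

  ζ<sub>PPA1</sub> = PPA<sub>C1C2</sub> − PPA<sub>C1F</sub>,  ζ<sub>PPA2</sub> = PPA<sub>C2C1</sub> − PPA<sub>C2F</sub>,  ζ<sub>NPA1</sub> = NPA<sub>C1C2</sub> − NPA<sub>C1F</sub>,  ζ<sub>NPA2</sub> = NPA<sub>C2C1</sub> − NPA<sub>C2F</sub>

  with percentile-bootstrap (1000 replicates) or Newcombe method-10
  confidence intervals; Bayes/total-probability prevalence adjustment for
  enriched cohorts; and the non-inferiority decision ε < δ, where ε is the
  maximum upper 95% confidence limit over the ζ of a side (ε₁ predictive,
  ε₀ selective) and δ the pre-specified margin.
* **Analytical validation** — hit-rate limit of detection (lowest level with
  ≥ 95% detection, monotone tail), limit of blank with exact bounds,
  DNA-input concordance, EP05-style variance-component precision with %CV,
  VF-bucket call rates, and Deming errors-in-variables regression.
* **Signature callers** — MSI (≥ 39 frameshift loci of 5,721), TMB
  (eligible somatic mutations per Mb, high at ≥ 10), genomic LoH (% of 552
  segments; High ≥ 16%), LST (losses > 10 Mb), GSS, HRD (BRCA1/2 or
  GSS ≥ 46), and CNA classification against the 8.3-copy reliability bound.
* **Synthetic data generators** with known ground truth for every input, so
  the whole pipeline is testable without access to clinical samples.

## Worked example

Simulate an enriched concordance cohort whose follow-on test truly matches
the comparator (sensitivity 0.95, specificity 0.97 in both arms,
conditionally independent errors, 2% invalid calls), then run the full
analysis:

```r
library(cdxval)
cohort <- simulate_concordance_cohort(concordance_sim_spec(
  n_samples = 800, prevalence = 0.3, enrichment = 0.5,
  ccd_dependence = 0, invalid_rate = 0.02, seed = 7))
fit <- concordance(cohort, delta1 = 0.05, delta0 = 0.05,
                   n_boot = 1000, seed = 7, prevalence = 0.3)
print(fit)
```

```
Comparator-anchored concordance analysis (n = 755 analyzable)
  invalid policy: exclude (45 dropped, 0 recoded of 800 input rows)
  PPA C1F: 92.9% (89.5%, 95.3%) 289/311   NPA C1F: 91.7% (88.7%, 93.9%) 407/444
  PPA C1C2: 91.3% (87.7%, 94.0%) 284/311  NPA C1C2: 92.8% (90.0%, 94.8%) 412/444
zeta differences (CCD replicate agreement minus FCD agreement):
  ZETA_PPA1 -0.0161  [-0.0429, +0.0124] (percentile_bootstrap)
  ZETA_PPA2 -0.0380  [-0.0695, -0.0064] (percentile_bootstrap)
  ZETA_NPA1 +0.0113  [-0.0138, +0.0359] (percentile_bootstrap)
  ZETA_NPA2 +0.0068  [-0.0184, +0.0345] (percentile_bootstrap)
predictive: epsilon1 = 0.0124 vs delta1 = 0.0500  -> PASS
selective:  epsilon0 = 0.0359 vs delta0 = 0.0500  -> PASS
overall non-inferiority: PASS
prevalence-adjusted agreement vs ccd1 (population prevalence 0.300):
  PPA_adj = 89.7%   NPA_adj = 93.6%
```

Reading the output: 45 of 800 samples had an invalid call somewhere and were
excluded. The FCD agrees with CCD1 on 92.9% of CCD1-positive samples —
essentially the comparator's own replicate agreement (91.3%), so every ζ is
near zero. The largest upper confidence limit on each side (ε₁ = 0.0124,
ε₀ = 0.0359) stays strictly below the 0.05 margin, so the follow-on test is
declared non-inferior. The last block reweights agreement to a 30%
population prevalence of the pre-test marker.

Signature calling works the same way from tables:

```r
s <- simulate_signature_sample(signature_sim_spec(
  msi_frameshift_count = 45, eligible_mutation_count = 360,
  loh_segment_count = 100, lst_loss_lengths_mb = c(12, 15, 22, 8),
  seed = 1))
call_signatures(s$variants, s$msi_table, s$loh_table, s$cn_segments,
                s$snps_read, s$sample_depth, s$brca_status)
#> genomic signature calls:
#>   MSI: MSI_high
#>   TMB: 12.00 mut/Mb (high, 360 eligible)
#>   genomic LoH: 18.1% (High)
#>   LST: 3
#>   GSS: 21.1 (assumed combination)
#>   HRD: negative (BRCA wild_type)
```

See `vignettes/cdx-validation-statistics.Rmd` for the model, assumptions,
boundary semantics and design choices.

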