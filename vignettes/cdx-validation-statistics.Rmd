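---
title: "Concordance and analytical-validation statistics for companion diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance and analytical-validation statistics for companion diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdxval)
```

## The problem

When a new tumor-profiling assay seeks approval as a follow-on companion
diagnostic (FCD), there is usually no gold standard to compare against: the
approved comparator companion diagnostic (CCD) is itself an imperfect test.
The accepted design runs each sample once on the new test and twice on the
comparator, and asks whether the new test agrees with a comparator replicate
*as well as the comparator agrees with itself*. cdxval implements the
statistics of that design, the surrounding analytical-validation estimators
(limit of detection and blank, DNA-input concordance, within-lab precision,
Deming method comparison), and the deterministic genomic signature callers
(MSI, TMB, genomic LoH, LST, GSS, HRD, CNA class) that produce the
qualitative calls being compared.

## The concordance model

Each sample contributes a triple of qualitative calls (CCD1, CCD2, FCD).
Positive percent agreement between a reference arm and a test arm is the
proportion of reference-positive samples on which the test arm is positive
(NPA conditions on reference-negatives). Four agreement differences are
formed:

\[
\zeta_{PPA1} = PPA_{C1C2} - PPA_{C1F},\qquad
\zeta_{PPA2} = PPA_{C2C1} - PPA_{C2F},
\]
\[
\zeta_{NPA1} = NPA_{C1C2} - NPA_{C1F},\qquad
\zeta_{NPA2} = NPA_{C2C1} - NPA_{C2F}.
\]

A zeta near zero means the new test replaces a comparator replicate without
loss. The observed margin \(\varepsilon\) is the maximum upper 95%
confidence limit over the zetas of a side (\(\varepsilon_1\) predictive,
\(\varepsilon_0\) selective), and non-inferiority is achieved when
\(\varepsilon < \delta\), the pre-specified target margin, with strict
inequality. Two useful exact identities follow from the definitions: when
the FCD calls are a copy of CCD2, \(\zeta_{PPA1} = \zeta_{NPA1} = 0\)
(both terms condition on CCD1 and compare an identical arm), and
symmetrically the C2-anchored zetas vanish when FCD copies CCD1. The test
suite uses these as exact oracles.

Which pair of zetas carries the predictive claim is not intrinsic to the
arithmetic — a claim that selects patients on a *negative* result reverses
the roles — so `noninferiority_decision()` maps the predictive side to the
PPA zetas by default and lets the caller swap the mapping.

### Confidence intervals

* Single proportions use the Wilson score interval by default. This choice
  reproduces the closed form \(n/(n+z^2)\) for perfect agreement
  (e.g. 14/14 gives a 78.5% lower bound), which matches how perfect-agreement
  rows are conventionally reported. The exact Clopper-Pearson interval
  (lower bound \((\alpha/2)^{1/n}\) at \(x=n\)) and a continuity-corrected
  Wilson interval are selectable; the two families disagree slightly and the
  package deliberately exposes both rather than resolving the difference.
* Zeta differences use a percentile bootstrap with 1000 replicates by
  default: whole sample triples are resampled with replacement and the
  empirical \(\alpha/2\) and \(1-\alpha/2\) quantiles (linear interpolation,
  quantile type 7) are taken. Because every zeta depends on the data only
  through the counts of the eight (CCD1, CCD2, FCD) call patterns,
  resampling is implemented by drawing pattern counts from a multinomial
  distribution — distributionally identical to row resampling and fast
  enough that coverage studies run in seconds. Replicates on which a zeta is
  undefined (its reference denominator resampled to zero) are skipped and
  counted; more than 50% undefined replicates is treated as an unstable
  margin and raised as an error rather than smoothed over.
* For unenriched designs (e.g. wild-type selection claims enrolled
  without enrichment) a closed-form
  interval is provided instead: Newcombe's method 10 for a paired difference
  of proportions, built from continuity-corrected Wilson limits on the two
  marginal proportions combined square-and-add style with a
  continuity-corrected estimate of the within-pair correlation \(\phi\).
  The published description of this method is brief; the transcription used
  here is validated in the tests against an independent literal
  implementation of the formula and by a paired-binomial coverage
  simulation (coverage at or above 93% at \(n = 200\)).

### Enrichment and prevalence adjustment

Cohorts for rare markers are enriched with pre-test positives, so raw
agreement does not describe the intended-use population. The adjustment
implemented estimates the joint distribution of (comparator call, FCD call)
separately within the pre-test-positive and pre-test-negative strata,
reweights the strata to an assumed population prevalence of the pre-test
marker by the law of total probability, and recomputes
\(PPA = P(F^+ \wedge C^+)/P(C^+)\) (and symmetrically NPA) by Bayes'
theorem. This interprets a construction the source material states only by
name; the interpretation assumes the within-stratum joint distribution is
transportable to the population, and it reduces exactly to the unadjusted
estimates when the assumed prevalence equals the observed stratum fraction
(checked to 1e-12 in the tests).

### Invalid results

The primary analysis excludes any sample with an invalid call on either
assay. Best- and worst-case sensitivity analyses instead keep such samples
and recode the invalid calls to the values that maximize or minimize
within-sample agreement; recoding resolves invalid calls deterministically
in arm order against the already-resolved calls of the row, so reruns are
identical.

## Analytical validation estimators

**Limit of detection** uses the empirical hit-rate rule: the LoD is the
lowest tested level with a detection rate of at least 95%, with the
additional *monotone-tail* requirement that all higher levels also qualify.
The tail rule is this package's tie-break for non-monotone observed rates,
which the empirical rule alone leaves ambiguous. No probit/logistic fit is
performed for the estimate itself; the logistic model appears only in the
synthetic generator, where the 95%-detection quantile is placed exactly at
the simulated true LoD so recovery can be scored.

**Limit of blank** pools false-positive calls per variant class over
wild-type samples, with exact binomial intervals; zero-call classes report
the one-sided exact upper bound \(1-(1-\gamma)^{1/n}\).

**Within-lab precision** decomposes replicate variance into
operator/instrument, reagent lot, between-run and within-run components by
method-of-moments ANOVA on a balanced design (operators crossed with lots,
runs nested in cells, replicates within runs), with negative estimates
truncated to zero before totaling — the CLSI EP05-style estimator. REML is
deliberately not used: the method-of-moments estimator is the conventional
one for these panels and keeps every reported component an explicit
function of mean squares. %CV is \(100 \cdot SD_{total}/\bar{y}\) and is an
error at zero mean rather than an infinity. Operator teams and instrument
sets are confounded in the emulated design (team *i* uses instrument set
*i*), so they are reported as a single component.

**DNA-input concordance** compares challenge-input calls to control-input
calls per alteration class with exact intervals, and summarizes quantitative
TMB as the mean absolute percent difference across paired samples with a
percentile-bootstrap upper bound over samples.

**Deming regression** uses the closed-form errors-in-variables slope for a
given error-variance ratio \(\lambda\) (y-error over x-error, default 1,
i.e. orthogonal regression), converging to ordinary least squares as
\(\lambda \to \infty\) — both facts are verified numerically in the tests
against an independent minimization of the errors-in-variables loss.

## Signature callers and their thresholds

| Signature | Rule | Boundary semantics |
|---|---|---|
| MSI | frameshift-mutated loci out of 5,721 | high at \(\ge\) 39, inclusive |
| TMB | eligible somatic mutations / footprint (Mb) | high at \(\ge\) 10 /Mb, inclusive |
| genomic LoH | % of 552 segments with LoH | High \(\ge\) 16%, Equivocal 11–15%, Low < 11% on the integer-rounded percent; Indeterminate at \(\le\) 3,000 SNPs or depth < 200× |
| LST | loss segments | strictly > 10 Mb |
| GSS | combination of LoH and LST evidence | HRD-high at \(\ge\) 46, inclusive |
| HRD | BRCA1/2 pathogenic OR GSS-high | disjunctive |
| CNA | estimated copies vs caller threshold | 8.3 copies is the validated reliable-detection bound |

TMB eligibility counts missense, nonsense, in-frame indel and frameshift
variants with *no* germline evidence; germline filtering consumes
pre-annotated flags (dbSNP151, gnomAD AC>0, curated benign) on the variant
records rather than querying databases, so results are reproducible across
database versions. The assay footprint (Mb) is a required configuration
value; 30 Mb, a conventional whole-exome footprint, is the default and an
assumption.

Two pieces are explicitly assumptions of this package, kept in their own
functions so they can be bypassed: the per-segment LoH rule (a segment is
LoH when the mean major-allele fraction of its heterozygous SNPs is at
least 0.75, with segments under 17 SNPs/Mb flagged low-confidence), and the
GSS combination (LoH segments scaled to the 0–100 percent scale plus one
point per LST). The GSS formula is unpublished; results carry a
`formula_assumed` flag, the weights are configurable, and the HRD rule
itself (BRCA OR GSS \(\ge\) 46) is exact regardless of the combination
chosen.

## What the synthetic data emulate — and what they do not

`simulate_concordance_cohort()` draws a latent biomarker truth at a set
prevalence, models enrollment as stratified sampling on a noisy pre-test
marker (truths within strata follow Bayes' rule, so the enriched cohort's
composition is exactly consistent with the population model), and generates
arm calls through per-arm sensitivity/specificity. Dependence between the
two comparator replicates is a shared-error mixture: with probability
\(\rho\) both replicates reuse one error draw, making \(\rho\) the
correlation of the replicate error indicators. The follow-on test errs
conditionally independently. Invalid results arrive independently per call.

This emulates the *statistical* structure of an enriched paired-comparator
study with known truth, which is what the estimators need. It does not
emulate real-data features such as tumor-type mixtures, borderline analyte
levels near a calling threshold (the main driver of real replicate
discordance), systematic (rather than exchangeable) error modes, or
correlated invalidity — so passing simulation checks demonstrates that the
statistics behave as designed under their assumptions, not that any
particular assay meets its margins.

Default generator settings are one choice of realistic conditions: CCD
sensitivity/specificity 0.95/0.97, replicate error correlation 0.3,
prevalence 0.3, and 50% enrichment where enrichment is used. The precision
generator's default design (3 operators × 3 lots, 2 runs per cell, 2
replicates per run = 36 replicates per panel member) mirrors a full
within-lab study.

## Numerical choices and problem sizes

* Percentages are displayed to one decimal with half-up rounding; all
  internal computation is at full precision.
* Every stochastic routine takes an explicit integer seed, restores the
  caller's RNG state, and records the seed in its result; JSON reports
  embed the seed and a hash of the configuration, and identical inputs
  produce byte-identical documents.
* The test and acceptance simulations use: bootstrap coverage at
  \(n = 300\) cohorts, 500 simulations, 1000 bootstrap replicates;
  non-inferiority operating characteristic at \(n = 2000\), 200
  simulations; LoD recovery over 500 logistic series at 20
  replicates/level; precision recovery over 200 panels of 36 replicates.
  These sizes give Monte-Carlo standard errors of roughly 1% on coverage
  and pass-rate estimates, matched to the ±3% acceptance bands.

## Known limitations

* Non-inferiority margins \(\delta_1, \delta_0\) are claim-specific inputs;
  no defaults beyond the illustrative 0.05 are asserted.
* The bootstrap is unstratified (whole triples); a stratified bootstrap for
  heavily enriched designs is not provided.
* Variance decomposition requires (near-)balance; strongly unbalanced
  designs would need REML, which is out of scope.
* No multiplicity adjustment across claims, and no power/sample-size
  machinery beyond the simulation helpers.
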