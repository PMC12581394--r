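Package: cdxval
Title: Concordance and Analytical Validation Statistics for Companion Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for validating a follow-on companion
    diagnostic (CDx) against an approved comparator when no gold standard is
    available: positive/negative percent agreement with Wilson and
    Clopper-Pearson intervals, paired agreement differences (zeta) with
    percentile-bootstrap and Newcombe method-10 confidence intervals,
    prevalence adjustment for enriched cohorts, and the epsilon-versus-delta
    non-inferiority decision. Also provides analytical-validation statistics
    (hit-rate limit of detection, limit of blank, DNA-input concordance,
    variance-component precision with percent CV, Deming regression) and
    genomic signature callers (microsatellite instability, tumor mutational
    burden, genomic loss of heterozygosity, large-scale state transitions,
    genomic scar score, homologous recombination deficiency, copy-number
    amplification), together with synthetic-data generators with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
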