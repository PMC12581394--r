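test_that("cohort generation is bit-reproducible under a fixed seed", {
  spec <- concordance_sim_spec(n_samples = 200, invalid_rate = 0.05,
                               enrichment = 0.5, seed = 17)
  a <- simulate_concordance_cohort(spec)
  b <- simulate_concordance_cohort(spec)
  expect_identical(a, b)
  spec2 <- concordance_sim_spec(n_samples = 200, invalid_rate = 0.05,
                                enrichment = 0.5, seed = 18)
  expect_false(identical(simulate_concordance_cohort(spec2)$fcd, a$fcd))
})

test_that("perfect assays yield fully concordant cohorts with zero zetas", {
  spec <- concordance_sim_spec(n_samples = 300, ccd_se = 1, ccd_sp = 1,
                               fcd_se = 1, fcd_sp = 1, invalid_rate = 0,
                               seed = 4)
  tab <- simulate_concordance_cohort(spec)
  truth <- attr(tab, "truth")
  expect_equal(tab$ccd1, ifelse(truth, "positive", "negative"))
  expect_equal(tab$ccd1, tab$fcd)
  z <- zeta_differences(tab)
  for (nm in names(z)) expect_identical(z[[nm]]$point, 0)
})

test_that("invalid_rate one makes every call invalid", {
  spec <- concordance_sim_spec(n_samples = 50, invalid_rate = 1, seed = 2)
  tab <- simulate_concordance_cohort(spec)
  expect_true(all(unlist(tab[, c("ccd1", "ccd2", "fcd")]) == "invalid"))
})

test_that("empirical agreement matches the total-probability closed form", {
  spec <- concordance_sim_spec(n_samples = 10000, prevalence = 0.3,
                               ccd_se = 0.97, ccd_sp = 0.99,
                               fcd_se = 0.95, fcd_sp = 0.98,
                               ccd_dependence = 0, seed = 23)
  tab <- simulate_concordance_cohort(spec)
  ppa <- pairwise_agreement(tab, "ccd1", "fcd", "PPA")
  # closed form: P(F+ | C1+) by total probability over latent truth
  pi <- 0.3
  p_c1 <- 0.97 * pi + 0.01 * (1 - pi)
  p_both <- 0.97 * 0.95 * pi + 0.01 * 0.02 * (1 - pi)
  expect_lt(abs(ppa$estimate - p_both / p_c1),
            3 * sqrt(0.05 * 0.95 / (p_c1 * 10000)))
  # and the packaged closed form agrees with a direct transcription
  ez <- expected_zetas(spec)
  p_c1c2 <- 0.97^2 * pi + 0.01^2 * (1 - pi)
  expect_equal(unname(ez["zeta_ppa1"]), (p_c1c2 - p_both) / p_c1,
               tolerance = 1e-12)
})

test_that("matched FCD with independent errors has mean zeta near zero", {
  spec0 <- concordance_sim_spec(n_samples = 500, ccd_dependence = 0, seed = 0)
  expect_equal(unname(expected_zetas(spec0)), rep(0, 4), tolerance = 1e-12)
  set.seed(91)
  n_sim <- 200
  zmat <- vapply(seq_len(n_sim), function(i) {
    tab <- simulate_concordance_cohort(
      concordance_sim_spec(n_samples = 500, ccd_dependence = 0))
    vapply(zeta_differences(tab), function(z) z$point, numeric(1))
  }, numeric(4))
  zbar <- rowMeans(zmat)
  mc_se <- apply(zmat, 1, sd) / sqrt(n_sim)
  expect_true(all(abs(zbar) < 3 * mc_se))
})

test_that("replicate dependence raises comparator self-agreement", {
  dep <- expected_zetas(concordance_sim_spec(ccd_dependence = 0.5))
  expect_true(all(dep > 0)) # shared errors make C1C2 exceed C1F agreement
})

test_that("precision panels honor the design and degenerate cases", {
  p <- simulate_precision_panel(mean = 7, seed = 5)
  expect_equal(nrow(p), 36) # 3 x 3 cells, 2 runs, 2 replicates
  expect_equal(length(unique(p$operator)), 3)
  expect_identical(p$instrument, sub("OP", "INST", p$operator))
  const <- simulate_precision_panel(mean = 7, sigma_resid = 0, seed = 5)
  expect_true(all(const$value == 7))
  expect_error(simulate_precision_panel(sigma_resid = -1), ">= 0")
  # law of large numbers: %CV near 100 * sigma / mean on a large design
  big <- simulate_precision_panel(mean = 10, sigma_resid = 1,
                                  n_operators = 10, n_lots = 10,
                                  runs_per_cell = 3, reps_per_run = 3,
                                  seed = 77)
  vc <- variance_components(big)
  expect_lt(abs(vc$cv_percent - 10), 1.5)
})

test_that("infeasible simulation parameters are rejected", {
  expect_error(concordance_sim_spec(ccd_se = 1.2), "probabilities")
  expect_error(concordance_sim_spec(n_samples = 0), "n_samples")
  expect_error(concordance_sim_spec(enrichment = 1), "enrichment")
})
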