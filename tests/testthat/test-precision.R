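test_that("a constant panel has zero variance everywhere", {
  panel <- simulate_precision_panel(mean = 12, sigma_resid = 0, seed = 1)
  vc <- variance_components(panel)
  expect_equal(unname(vc$components), rep(0, 4))
  expect_equal(vc$cv_percent, 0)
  expect_equal(vc$mean, 12)
})

test_that("a one-factor balanced fixture matches the textbook ANOVA solution", {
  # operators A (values 1, 3) and B (5, 7), one run each:
  # MS_within = 2, MS_between = 16, sigma2_op = (16 - 2)/2 = 7
  panel <- data.frame(operator = c("A", "A", "B", "B"), lot = "L1",
                      run = "R1", value = c(1, 3, 5, 7))
  vc <- variance_components(panel)
  expect_equal(vc$components[["within_run"]], 2)
  expect_equal(vc$components[["operator_instrument"]], 7)
  expect_equal(vc$components[["reagent_lot"]], 0)
  expect_equal(vc$components[["between_run"]], 0)
  expect_equal(vc$total_variance, 9)
  expect_match(paste(vc$flags, collapse = ";"), "lot")
})

test_that("total variance is the sum of components and scaling leaves %CV fixed", {
  panel <- simulate_precision_panel(mean = 10, sigma_operator = 0.3,
                                    sigma_lot = 1, sigma_run = 0.5,
                                    sigma_resid = 0.25, seed = 21)
  vc <- variance_components(panel)
  expect_equal(vc$total_variance, sum(vc$components), tolerance = 1e-9)
  scaled <- panel
  scaled$value <- panel$value * 3.7
  vc2 <- variance_components(scaled)
  expect_equal(vc2$total_sd, vc$total_sd * 3.7, tolerance = 1e-9)
  expect_equal(vc2$cv_percent, vc$cv_percent, tolerance = 1e-9)
})

test_that("method-of-moments recovers simulated components on average", {
  set.seed(31)
  n_sim <- 60
  est <- replicate(n_sim, {
    p <- simulate_precision_panel(mean = 10, sigma_lot = 1, sigma_run = 0.5,
                                  sigma_resid = 0.25)
    variance_components(p)$total_sd
  })
  true_sd <- sqrt(1 + 0.5^2 + 0.25^2)
  expect_lt(abs(mean(est) - true_sd) / true_sd, 0.15)
})

test_that("residual-only panels attribute variance to within-run", {
  set.seed(8)
  p <- simulate_precision_panel(mean = 10, sigma_resid = 1,
                                n_operators = 3, n_lots = 3,
                                runs_per_cell = 3, reps_per_run = 4)
  vc <- variance_components(p)
  expect_gt(vc$components[["within_run"]] / vc$total_variance, 0.7)
})

test_that("%CV is an error when the mean is zero and replicates are required", {
  zero <- data.frame(operator = c("A", "A", "B", "B"), lot = "L", run = "R",
                     value = c(-1, 1, -1, 1))
  expect_error(variance_components(zero), "mean is zero")
  single <- data.frame(operator = c("A", "B"), lot = "L", run = "R",
                       value = c(1, 2))
  expect_error(variance_components(single), "2 replicates")
})

test_that("VF-bucket call rates pool nested buckets correctly", {
  calls <- data.frame(vf = c(5, 8, 10, 15), detected = c(35, 36, 36, 36),
                      replicates = 36)
  rates <- vf_bucket_precision(calls)
  expect_equal(rates$call_rate[rates$vf_min == 5],
               (35 + 36 + 36 + 36) / (4 * 36))
  expect_equal(rates$call_rate[rates$vf_min == 15], 1)
  # one 5%-VF variant detected 35/36 in its own bucket
  one <- vf_bucket_precision(data.frame(vf = 5, detected = 35,
                                        replicates = 36),
                             buckets = 5)
  expect_equal(round(100 * one$call_rate, 1), 97.2)
  # empty bucket is undefined, not zero
  empty <- vf_bucket_precision(data.frame(vf = 5, detected = 30,
                                          replicates = 36))
  expect_true(is.na(empty$call_rate[empty$vf_min == 15]))
})

test_that("bucket rates are monotone when detection is monotone in VF", {
  vf <- c(5, 6, 8, 9, 10, 12, 15, 20)
  p <- plogis((vf - 6) / 2)
  calls <- data.frame(vf = vf, detected = round(36 * p), replicates = 36)
  rates <- vf_bucket_precision(calls)$call_rate
  expect_true(all(diff(rates[!is.na(rates)]) >= -1e-12))
})
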