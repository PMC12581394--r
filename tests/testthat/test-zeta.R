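test_that("zetas anchored on a replicated arm vanish exactly", {
  # zetaPPA1 compares CCD2 and FCD against CCD1-positive samples, so it is
  # identically zero when FCD copies CCD2; the C2-anchored zetas vanish
  # when FCD copies CCD1
  set.seed(101)
  for (rep in 1:20) {
    n <- 30
    c1 <- sample(c("positive", "negative"), n, replace = TRUE)
    c2 <- sample(c("positive", "negative"), n, replace = TRUE)
    if (!all(c("positive", "negative") %in% c1) ||
        !all(c("positive", "negative") %in% c2)) next
    copy_c2 <- paired_call_table(seq_len(n), c1, c2, c2)
    z <- zeta_differences(copy_c2)
    expect_identical(z$zeta_ppa1$point, 0)
    expect_identical(z$zeta_npa1$point, 0)
    copy_c1 <- paired_call_table(seq_len(n), c1, c2, c1)
    z2 <- zeta_differences(copy_c1)
    expect_identical(z2$zeta_ppa2$point, 0)
    expect_identical(z2$zeta_npa2$point, 0)
  }
})

test_that("zeta points equal the defining subtraction and the brute-force tally", {
  # 12-row fixture with a single CCD2/FCD discordance
  tab <- table_from_patterns(c("ppp", "pnp", "nnn", "nnp"), c(5, 1, 5, 1))
  z <- zeta_differences(tab)
  oracle <- brute_zetas(tab)
  for (nm in names(oracle))
    expect_equal(z[[nm]]$point, oracle[[nm]], tolerance = 1e-12)
  # arithmetic on stated agreement values
  expect_equal(0.98 - 0.97, 0.01, tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:10) {
    rnd <- table_from_patterns(
      c("ppp", "ppn", "pnp", "pnn", "npp", "npn", "nnp", "nnn"),
      rpois(8, 3) + 1)
    got <- zeta_differences(rnd)
    ref <- brute_zetas(rnd)
    for (nm in names(ref)) expect_equal(got[[nm]]$point, ref[[nm]])
  }
})

test_that("undefined component agreements are reported by name", {
  all_pos <- table_from_patterns("ppp", 4)
  expect_error(zeta_differences(all_pos), "zeta_npa")
})

test_that("bootstrap is degenerate on all-concordant tables and seed-stable", {
  tab <- table_from_patterns(c("ppp", "nnn"), c(12, 14))
  z <- bootstrap_zeta_ci(tab, n_boot = 200, seed = 5)
  for (nm in names(z)) {
    expect_identical(z[[nm]]$ci_low, 0)
    expect_identical(z[[nm]]$ci_high, 0)
  }
  mixed <- table_from_patterns(c("ppp", "ppn", "npp", "nnn"), c(8, 2, 1, 9))
  a <- bootstrap_zeta_ci(mixed, n_boot = 200, seed = 99)
  b <- bootstrap_zeta_ci(mixed, n_boot = 200, seed = 99)
  expect_identical(a, b)
  c2 <- bootstrap_zeta_ci(mixed, n_boot = 200, seed = 100)
  expect_false(identical(a, c2))
  expect_error(bootstrap_zeta_ci(mixed, n_boot = 1), "n_boot")
})

test_that("replicates with empty denominators are skipped and counted", {
  sparse <- table_from_patterns(c("ppp", "nnn"), c(1, 3))
  z <- bootstrap_zeta_ci(sparse, n_boot = 500, seed = 1)
  skipped <- attr(z, "n_skipped")
  expect_true(sum(skipped) > 0) # ~32% of resamples lose the only positive
  expect_true(all(is.finite(vapply(z, function(x) x$ci_high, numeric(1)))))
})

test_that("method-10 interval matches a literal transcription of the formula", {
  tab <- table_from_patterns(c("ppp", "ppn", "pnp", "nnn"), c(40, 3, 1, 56))
  got <- newcombe10_paired_diff_ci(tab, "ccd2", "fcd", "PPA")
  # independent transcription on the paired 2x2 (e, f, g, h)
  e <- 40; f <- 3; g <- 1; h <- 56 # paired (ccd2, fcd) counts from the fixture
  n <- e + f + g + h
  z <- qnorm(0.975)
  wcc <- function(x) {
    p <- x / n
    lo <- if (x == 0) 0 else
      (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n +
                                        4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
    hi <- if (x == n) 1 else
      (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n +
                                        4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
    c(max(0, lo), min(1, hi))
  }
  p1 <- (e + f) / n; p2 <- (e + g) / n
  w1 <- wcc(e + f); w2 <- wcc(e + g)
  num <- e * h - f * g
  if (num > 0) num <- max(num - n / 2, 0)
  phi <- num / sqrt((e + f) * (g + h) * (e + g) * (f + h))
  dl1 <- p1 - w1[1]; du1 <- w1[2] - p1
  dl2 <- p2 - w2[1]; du2 <- w2[2] - p2
  low <- (p1 - p2) - sqrt(dl1^2 - 2 * phi * dl1 * du2 + du2^2)
  high <- (p1 - p2) + sqrt(du1^2 - 2 * phi * du1 * dl2 + dl2^2)
  expect_equal(got$diff, p1 - p2, tolerance = 1e-12)
  expect_equal(got$low, low, tolerance = 1e-12)
  expect_equal(got$high, high, tolerance = 1e-12)
})

test_that("method-10 interval straddles zero for identical arms", {
  tab <- table_from_patterns(c("ppp", "nnn"), c(25, 25))
  ci <- newcombe10_paired_diff_ci(tab, "ccd1", "fcd", "PPA")
  expect_equal(ci$diff, 0)
  expect_lt(ci$low, 0)
  expect_gt(ci$high, 0)
  expect_error(newcombe10_paired_diff_ci(table_from_patterns("ppp", 1),
                                         "ccd1", "fcd", "PPA"),
               "fewer than 2")
})

test_that("method-10 coverage reaches nominal level in paired simulation", {
  # paired binary outcomes with shared latent success driver
  set.seed(2024)
  n <- 200; n_sim <- 1000
  p1 <- 0.90; p2 <- 0.85
  covered <- 0L
  for (s in seq_len(n_sim)) {
    u <- runif(n)
    x <- u < p1                       # arm a positive
    y <- (u < p2) | (runif(n) < 0.03) # correlated arm b
    py <- p2 + (1 - p2) * 0.03
    truth <- p1 - py
    tab <- paired_call_table(seq_len(n),
                             ifelse(x, "positive", "negative"),
                             rep("negative", n),
                             ifelse(y, "positive", "negative"))
    ci <- newcombe10_paired_diff_ci(tab, "ccd1", "fcd", "PPA")
    if (ci$low <= truth && truth <= ci$high) covered <- covered + 1L
  }
  expect_gte(covered / n_sim, 0.93)
})

test_that("zeta-wise method-10 intervals cover the zeta points", {
  tab <- table_from_patterns(c("ppp", "ppn", "pnp", "npp", "nnn", "nnp"),
                             c(30, 3, 2, 2, 40, 2))
  zs <- zeta_newcombe_ci(tab)
  pts <- brute_zetas(tab)
  for (nm in names(pts)) {
    expect_equal(zs[[nm]]$point, pts[[nm]], tolerance = 1e-12)
    expect_lte(zs[[nm]]$ci_low, zs[[nm]]$point)
    expect_gte(zs[[nm]]$ci_high, zs[[nm]]$point)
    expect_identical(zs[[nm]]$method, "newcombe10")
  }
})
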