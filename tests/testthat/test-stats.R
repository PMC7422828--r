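grid_r <- build_grid("right")

test_that("mean sensitivity averages the 44 test points only", {
  loc <- data.frame(role = grid_r$role, dls_db = rep(20, 46))
  expect_equal(mean_sensitivity(loc), 20)
  # blind-spot values have no influence at all
  loc$dls_db[grid_r$role == "blind_spot"] <- c(0, 34)
  expect_equal(mean_sensitivity(loc), 20)
  loc$dls_db[grid_r$role == "test"] <- (0:43) / 43 * 34
  expect_equal(mean_sensitivity(loc), mean((0:43) / 43 * 34))
})

test_that("Bland-Altman limits are the mean difference +/- 1.96 SD", {
  ba0 <- bland_altman(c(19, 20, 21), c(19, 20, 21))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$cor95, 0)
  ba <- bland_altman(c(10, 10), c(11, 9))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$cor95, qnorm(0.975) * sqrt(2))
  # adding a constant shifts the mean difference, never the coefficient
  r1 <- rnorm(30, 20); r2 <- r1 + rnorm(30, 0, 0.5)
  expect_equal(bland_altman(r1, r2 + 3)$mean_difference,
               bland_altman(r1, r2)$mean_difference + 3)
  expect_equal(bland_altman(r1, r2 + 3)$cor95, bland_altman(r1, r2)$cor95)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman agrees with explicit loop arithmetic", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(3:80, 1)
    r1 <- rnorm(n, 20, 2); r2 <- r1 + rnorm(n, 0.2, 1.3)
    ba <- bland_altman(r1, r2)
    # independent oracle: accumulate sums the long way
    s <- 0; for (i in seq_len(n)) s <- s + (r2[i] - r1[i])
    m <- s / n
    ss <- 0; for (i in seq_len(n)) ss <- ss + ((r2[i] - r1[i]) - m)^2
    cor_oracle <- 1.959963984540054 * sqrt(ss / (n - 1))
    expect_equal(ba$mean_difference, m, tolerance = 1e-12)
    expect_equal(ba$cor95, cor_oracle, tolerance = 1e-12)
    expect_equal(unname(ba$limits_of_agreement), c(m - cor_oracle, m + cor_oracle),
                 tolerance = 1e-12)
  }
})

test_that("BCa intervals are seed-deterministic and permutation-invariant", {
  set.seed(2)
  x <- rnorm(40, 5, 2)
  a <- bca_bootstrap_ci(x, mean, n_boot = 2000, seed = 42)
  b <- bca_bootstrap_ci(x, mean, n_boot = 2000, seed = 42)
  expect_identical(a, b)
  p <- bca_bootstrap_ci(sample(x), mean, n_boot = 2000, seed = 42)
  expect_identical(a$ci, p$ci)
  # interval brackets the point estimate
  expect_lt(a$ci["lower"], mean(x))
  expect_gt(a$ci["upper"], mean(x))
  # constant data: zero-width interval
  k <- bca_bootstrap_ci(rep(3, 20), mean, n_boot = 500, seed = 1)
  expect_equal(unname(k$ci), c(3, 3))
})

test_that("BCa reduces to the percentile interval for symmetric distributions", {
  # a perfectly symmetric bootstrap distribution has no bias or skew, so the
  # adjusted quantiles are the plain ones
  set.seed(3)
  x <- c(-rev(seq(0.1, 2, length.out = 20)), seq(0.1, 2, length.out = 20))
  r <- bca_bootstrap_ci(x, mean, n_boot = 4000, seed = 11)
  expect_lt(abs(r$z0), 0.05)
  expect_lt(abs(r$acceleration), 0.01)
  pct <- quantile(with_boot_stats(x, mean, 4000, 11), c(0.025, 0.975),
                  names = FALSE, type = 7)
  expect_lt(max(abs(unname(r$ci) - pct)), 0.025)
})

test_that("BCa matches the boot package on a fixed sample", {
  skip_if_not_installed("boot")
  set.seed(8)
  x <- rexp(50, 0.3)   # skewed, so the BCa correction matters
  ours <- bca_bootstrap_ci(x, mean, n_boot = 20000, seed = 21)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(unname(ours$ci), ci, tolerance = 0.01)
  # and the BCa interval is visibly shifted from the naive percentile one
  pct <- quantile(with_boot_stats(x, mean, 20000, 21), c(0.025, 0.975),
                  names = FALSE, type = 7)
  expect_false(isTRUE(all.equal(unname(ours$ci), pct, tolerance = 1e-4)))
})

test_that("repeatability difference test behaves under null and alternative", {
  set.seed(9)
  n <- 64
  a1 <- rnorm(n, 20); a2 <- a1 + rnorm(n, 0, 1)
  # identical datasets: no difference, p near 1
  same <- cor_difference_test(a1, a2, a1, a2, n_boot = 2000, seed = 3)
  expect_equal(same$observed_difference, 0)
  expect_gt(same$p_value, 0.9)
  expect_lte(same$p_value, 1)
  # device A three times noisier: detected
  for (s in 1:5) {
    b1 <- rnorm(n, 20); b2 <- b1 + rnorm(n, 0, 1)
    c1 <- rnorm(n, 20); c2 <- c1 + rnorm(n, 0, 3)
    r <- cor_difference_test(c1, c2, b1, b2, n_boot = 2000, seed = s)
    expect_lt(r$p_value, 0.05)
    expect_gt(r$observed_difference, 0)
  }
  expect_error(cor_difference_test(1, 2, 1, 2), "at least 2")
})

test_that("pointwise comparison flags only truly shifted locations", {
  set.seed(16)
  n <- 30; m <- 44
  a <- matrix(rnorm(n * m, 20, 0.3), n, m)
  b <- a + matrix(rnorm(n * m, 0, 0.3), n, m)
  # identical-distribution data: nothing significant
  res0 <- pointwise_comparison(a, b, alpha = 0.01)
  expect_true(all(res0$direction == "none"))
  # a +10 dB shift at one location with tiny noise: exactly that one flags
  b2 <- b; b2[, 17] <- b2[, 17] - 10
  res <- pointwise_comparison(a, b2, alpha = 0.01)
  expect_true(res$significant[17])
  expect_identical(res$direction[17], "a_higher")
  expect_lte(sum(res$significant), 2)   # nothing else beyond rare noise
  # the Bonferroni threshold is alpha / m
  expect_true(all(res$p_value[res$significant] < 0.01 / 44))
  expect_true(all(res$p_value[!res$significant] >= 0.01 / 44))
})

test_that("normative tables report mean and interpolated 95% limits", {
  vals <- matrix(rep(17, 5 * 46), 5, 46)
  tab <- normative_table(vals, grid_r)
  expect_equal(nrow(tab), 46)
  expect_equal(tab$mean_db, rep(17, 46))
  expect_equal(tab$p2.5_db, tab$p97.5_db)
  # hand-checked linear interpolation on a 5-value toy column
  toy <- matrix(rep(c(1, 2, 3, 4, 5), 46), 5, 46)
  t2 <- normative_table(toy, grid_r)
  expect_equal(t2$p2.5_db[1], 1.1)
  expect_equal(t2$p97.5_db[1], 4.9)
})

test_that("minimum detectable difference matches the paired-t formula", {
  # the cohort arithmetic: 64 pairs, SD of paired differences 1.548 dB
  expect_equal(round(min_detectable_difference(64, 1.548, 0.05, 0.80), 2),
               0.55)
  expect_lt(min_detectable_difference(64, 1e-9), 1e-8)
  mdd <- vapply(c(8, 16, 32, 64, 128), min_detectable_difference,
                numeric(1), sd_paired_diff = 1.5)
  expect_true(all(diff(mdd) < 0))
})
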