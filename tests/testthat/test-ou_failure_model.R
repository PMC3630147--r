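test_that("the noiseless scheme follows its closed-form relaxation", {
  lam <- simulate_ou(beta = 0.2, mu = 0.05, sigma = 0, dt = 2, n = 12, seed = 1)
  k <- 0:11
  expect_equal(lam, 0.05 * (1 - (1 - 0.4)^k), tolerance = 1e-14)
  expect_identical(simulate_ou(0.2, 0.05, 0.01, 2, 30, seed = 9),
                   simulate_ou(0.2, 0.05, 0.01, 2, 30, seed = 9))
  expect_error(simulate_ou(0.6, 0.05, 0.01, 2, 10), "beta \\* dt < 1")
  expect_error(simulate_ou(0.2, 0.05, -1, 2, 10), "sigma")
})

test_that("the stationary tail of a long simulation averages to the mean", {
  lam <- simulate_ou(0.2, 0.05, 0.01, dt = 2, n = 1e4, seed = 4)
  expect_equal(mean(lam[-(1:100)]), 0.05, tolerance = 0.02)
})

test_that("estimation recovers the generator and is exact in the noiseless limit", {
  f0 <- estimate_ou(simulate_ou(0.2, 0.05, 0, 2, 30, seed = 1), 2)
  expect_lt(abs(f0$beta - 0.2), 1e-10)
  expect_lt(f0$sigma, 1e-12)
  expect_equal(f0$halflife * f0$beta, log(2), tolerance = 1e-14)

  med <- median(vapply(1:60, function(s)
    estimate_ou(simulate_ou(0.2, 0.05, 0.01, 2, 30, seed = s), 2)$beta, 0))
  expect_gt(med, 0.15)
  expect_lt(med, 0.25)
})

test_that("the noise-based moment route agrees with conditional least squares", {
  rel <- vapply(1:30, function(s) {
    lam <- simulate_ou(0.2, 0.05, 0.01, 2, 200, seed = s)
    a <- estimate_ou(lam, 2)$beta
    b <- estimate_ou(lam, 2, method = "noise_regression")$beta
    abs(b - a) / a
  }, 0)
  expect_lt(median(rel), 0.1)
})

test_that("fits outside the mean-reverting regime carry diagnostics, not errors", {
  # strongly anti-correlated levels: reversion at the sampling limit
  alt <- 0.05 + 0.012 * rep(c(1, -1), 15) + 0.0005 * sin(1:30)
  f <- estimate_ou(alt, 2)
  expect_true(f$mean_reverting)
  expect_match(f$diagnostic, "sampling limit")
  # a deterministic upward ramp has no reversion at all
  ramp <- seq(0.01, 0.2, length.out = 20)
  f2 <- estimate_ou(ramp + 1e-5 * sin(1:20), 2)
  expect_false(f2$mean_reverting)
  expect_match(f2$diagnostic, "no mean reversion")
  expect_error(estimate_ou(alt, c(0, 2, 5)), "length mismatch")
  jitter_grid <- (0:29) * 2
  jitter_grid[30] <- jitter_grid[30] + 1
  expect_error(estimate_ou(alt, jitter_grid), "non-uniform")
})

test_that("the median-unbiased correction tightens short-series recovery", {
  raw <- vapply(1:200, function(s)
    estimate_ou(simulate_ou(0.1, 0.05, 0.01, 2, 12, seed = s,
                            lambda0 = 0.05), 2)$beta, 0)
  corr <- vapply(1:200, function(s)
    estimate_ou(simulate_ou(0.1, 0.05, 0.01, 2, 12, seed = s,
                            lambda0 = 0.05), 2,
                bias_correction = TRUE)$beta, 0)
  expect_lt(abs(median(corr) - 0.1), abs(median(raw) - 0.1))
  expect_lt(abs(median(corr) - 0.1), 0.04)
})

test_that("trailing moving averages use the available prefix", {
  expect_equal(moving_average_mean(c(1, 2, 3, 4), 2), c(1, 1.5, 2.5, 3.5))
  expect_equal(moving_average_mean(5:1, 1), 5:1)
  expect_equal(moving_average_mean(rep(2, 8), 6), rep(2, 8))
  expect_error(moving_average_mean(1:3, 4), "window exceeds")
})

test_that("the drifting-mean law is recovered exactly from noise-free data", {
  t <- seq(0, 24, by = 2)
  y <- 0.02 + 0.3 / (30 - t)
  f <- fit_mean_drift(y, t, L = 32)
  expect_true(f$converged)
  expect_equal(unname(coef(f)[c("c0", "c1", "t_c")]), c(0.02, 0.3, 30),
               tolerance = 1e-6)
  # near-constant input degenerates gracefully
  fc <- fit_mean_drift(rep(0.05, 10) + 1e-9 * sin(1:10), seq(0, 18, 2), L = 22)
  expect_true(fc$converged)
  expect_lt(abs(fc$c1), 1e-6)
  expect_error(fit_mean_drift(y, t, L = 20), "< L")
})

test_that("regime labels form contiguous engraftment / mean-reverting / terminal blocks", {
  lam <- c(0.01, 0.02, simulate_ou(0.2, 0.05, 0.005, 2, 20, seed = 3,
                                   lambda0 = 0.05)[-(1:2)], 0.2, 0.3, 0.5)
  tt <- seq(0, by = 2, length.out = length(lam))
  ou <- estimate_ou(lam[3:20], 2)
  rg <- detect_regimes(lam, tt, ou)
  runs <- rle(rg$labels)
  expect_true(all(runs$values %in% c("E", "OU", "T")))
  expect_lte(length(runs$values), 3)
  expect_identical(runs$values, unique(rg$labels))
  expect_equal(rg$engraftment_end, 2)
  expect_false(is.na(rg$transition_time))
  expect_equal(nrow(rg$phase), length(lam) - 1)
  expect_error(detect_regimes(lam, tt, structure(list(mean_reverting = FALSE),
                                                 class = "ou_fit")),
               "mean-reverting")
})
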