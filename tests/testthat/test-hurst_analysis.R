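test_that("rescaled range is scale-invariant and validated", {
  set.seed(1)
  x <- rnorm(64)
  rs1 <- rescaled_range(x)
  rs2 <- rescaled_range(1000 * x)
  expect_equal(rs1$rs_values, rs2$rs_values, tolerance = 1e-12)
  expect_error(rescaled_range(rep(1, 20)), "sd = 0")
  expect_error(rescaled_range(x, window_sizes = c(4, 8)), "minimum window")
  expect_error(rescaled_range(x, window_sizes = c(8, 128)), "exceeds")
  expect_error(rescaled_range(x, mean_mode = "trend"), "aligned trend")
})

test_that("an alternating series has unit rescaled range at even windows", {
  x <- rep(c(1, -1), 16)
  rs <- rescaled_range(x, window_sizes = c(8, 16, 32), rs_mode = "prefix")
  # deviations are the series itself; cumulative sums bounce between 1 and 0
  expect_equal(rs$rs_values, rep(1, 3))
})

test_that("a supplied trend equal to the window mean reproduces uniform mode", {
  set.seed(2)
  x <- rnorm(32)
  u <- rescaled_range(x, window_sizes = 32L, rs_mode = "prefix")
  tr <- rescaled_range(x, window_sizes = 32L, rs_mode = "prefix",
                       mean_mode = "trend", trend = rep(mean(x), 32))
  expect_equal(u$rs_values, tr$rs_values, tolerance = 1e-12)
})

test_that("an exact power law in the rescaled range yields its exponent", {
  ws <- as.integer(2^(3:9))
  rs <- structure(list(window_sizes = ws, rs_values = as.numeric(ws)^0.3,
                       mean_mode = "uniform", rs_mode = "prefix"),
                  class = "rs_result")
  h <- hurst_exponent(rs, correction = "none")
  expect_equal(h$hurst, 0.3, tolerance = 1e-12)
  expect_equal(h$r_squared, 1, tolerance = 1e-12)
})

test_that("the corrected estimator is centred for white noise and separates fGn regimes", {
  Hw <- vapply(1:30, function(s) { set.seed(s); hurst_exponent(rnorm(1024))$hurst }, 0)
  expect_gt(median(Hw), 0.45)
  expect_lt(median(Hw), 0.58)
  H3 <- vapply(1:30, function(s) hurst_exponent(gen_fgn(1024, 0.3, seed = s))$hurst, 0)
  H7 <- vapply(1:30, function(s) hurst_exponent(gen_fgn(1024, 0.75, seed = s))$hurst, 0)
  expect_lt(abs(median(H3) - 0.3), 0.1)
  expect_lt(abs(median(H7) - 0.75), 0.1)
  expect_gt(median(H7) - median(H3), 0.2)
})

test_that("memory classification applies the half-band around one half", {
  expect_equal(classify_memory(c(0.3, 0.5, 0.7)),
               c("anti-persistent", "no-memory", "persistent"))
  expect_equal(classify_memory(0.46), "no-memory")
  expect_error(classify_memory(1.2), "0, 1")
})

test_that("mean reversion leaves an anti-persistent signature in hazard fluctuations", {
  frac <- mean(vapply(1:60, function(s) {
    lam <- simulate_ou(0.2, 0.05, 0.01, dt = 2, n = 30, seed = s,
                       lambda0 = 0.05)
    failure_rate_memory(lam)$hurst < 0.5
  }, TRUE))
  expect_gte(frac, 0.85)
})

test_that("the lifespan tendency of the Hurst exponent is recovered", {
  L <- seq(12, 58, length.out = 10)
  exact <- suppressWarnings(hurst_vs_lifespan_fit(L, 0.4 - 0.001 * L))
  expect_equal(exact$slope, -0.001, tolerance = 1e-12)

  set.seed(3)
  L38 <- runif(38, 10, 60)
  H38 <- vapply(seq_along(L38), function(i)
    hurst_exponent(gen_fgn(512, 0.5 - 0.004 * L38[i], seed = i * 7))$hurst, 0)
  fit <- hurst_vs_lifespan_fit(L38, H38)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_slope, 0.05)

  expect_error(hurst_vs_lifespan_fit(rep(30, 5), rep(0.4, 5)), "degenerate")
})

test_that("the corrected estimator tracks an independent corrected R/S implementation", {
  diffs <- vapply(1:15, function(s) {
    x <- as.numeric(gen_fgn(1024, 0.7, seed = s * 11))
    ours <- hurst_exponent(x, rs_mode = "segmented")$hurst
    ref <- pracma::hurstexp(x, display = FALSE)$Hal
    ours - ref
  }, 0)
  expect_lt(abs(median(diffs)), 0.1)
})
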