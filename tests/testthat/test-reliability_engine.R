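test_that("instantaneous rates are per-interval difference quotients", {
  k <- toy_kinetic()
  expect_equal(instantaneous_rates(k), c(5, 5, -5, -5))
  flat <- clonal_kinetic("f", c(0, 2, 4, 6), c(3, 3, 3, 3))
  expect_equal(instantaneous_rates(flat), c(0, 0, 0))
  expect_error(reliability_profile(flat), "degenerate")
})

test_that("the worked toy kinetic decomposes exactly", {
  p <- reliability_profile(toy_kinetic())
  expect_equal(p$norm_A, 40)
  expect_equal(p$failure_prob, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-14)
  expect_equal(p$reliability, c(1, 0.75, 0.5, 0.25, 0), tolerance = 1e-14)
  expect_equal(p$failure_density, rep(0.125, 4), tolerance = 1e-14)
  expect_equal(p$failure_rate, c(0.125, 1 / 6, 0.25, 0.5), tolerance = 1e-12)
})

test_that("a flat-then-drop kinetic loads all failure on the drop interval", {
  k <- clonal_kinetic("fd", c(0, 2, 4), c(10, 10, 0), n_min = 3L)
  p <- reliability_profile(k)
  expect_equal(p$failure_prob, c(0, 0, 1))
  expect_equal(p$failure_density, c(0, 0.5))
})

test_that("profiles conserve probability on arbitrary kinetics", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:25, 1)
    tt <- cumsum(c(0, stats::runif(n - 1, 0.5, 3)))
    y <- pmax(0, stats::runif(n, 0, 80))
    k <- clonal_kinetic(paste0("r", s), tt, y, n_min = 4L)
    p <- tryCatch(reliability_profile(k), error = function(e) NULL)
    if (is.null(p)) next
    expect_equal(p$reliability + p$failure_prob, rep(1, n), tolerance = 1e-12)
    expect_true(all(diff(p$reliability) <= 1e-12))
    expect_equal(sum(p$failure_density * diff(tt)), 1, tolerance = 1e-12)
    expect_true(all(p$failure_density >= 0))
    expect_true(all(p$failure_rate >= 0))
    expect_equal(p$failure_rate,
                 p$failure_density / p$reliability[-n], tolerance = 1e-12)
  }
})

test_that("the discrete hazard matches the negative log-reliability slope on fine grids", {
  L <- 40
  k <- gen_clone(L = L, peak_height = 30, noise_cv = 0, dt = L / 1e4,
                 lineage_weights = NULL, seed = 1)
  p <- reliability_profile(k)
  n <- length(p$times)
  R <- p$reliability
  keep <- which(R[-1] >= 0.1)          # log-form defined and hazard resolved
  lam_log <- (log(R[keep]) - log(R[keep + 1])) / diff(p$times)[keep]
  rel <- abs(p$failure_rate[keep] - lam_log) / lam_log
  expect_lt(max(rel), 1e-3)
})

test_that("truncation drops the requested elements and records itself", {
  p <- reliability_profile(toy_kinetic())
  t0 <- truncate_failure_rate(p, 0, 0)
  expect_equal(t0$failure_rate, p$failure_rate)
  expect_equal(t0$truncation, c(0, 0))
  t2 <- truncate_failure_rate(seq(0.1, 1, by = 0.1), 0, 2)
  expect_length(t2$failure_rate, 8)
  expect_equal(t2$truncation, c(0, 2))
  expect_error(truncate_failure_rate(seq_len(8), 5, 5), "removes the whole")
})

test_that("the common-cause balance inverts exactly at unclamped points", {
  # single-point worked value
  got <- infer_hsc_reliability(c(1, 0.5, 0), c(1, 0.5, 0), c(1, 0.5, 0),
                               c(1, 0.5, 0), times = c(0, 2, 4))
  expect_equal(got$reliability[2], 0.75)
  expect_equal(got$reliability[1], 1)   # 0/0 resolved to fully reliable

  for (s in 1:100) {
    n <- 12
    Rc <- random_reliability(n, s)
    Rt <- random_reliability(n, s + 1000)
    Rb <- random_reliability(n, s + 2000)
    Rm <- random_reliability(n, s + 3000)
    prof <- infer_hsc_reliability(Rc, Rt, Rb, Rm, times = 2 * (0:(n - 1)))
    Rh <- prof$reliability
    unclamped <- Rh > 0 & Rh < 1 & (1 - Rc) > 0
    lhs <- 1 - (1 - Rh) * (1 - Rc)
    rhs <- 1 - (1 - Rt) * (1 - Rb) * (1 - Rm)
    expect_lt(max(abs(lhs[unclamped] - rhs[unclamped])), 1e-12)
    expect_true(all(Rh >= 0 & Rh <= 1))
  }
})

test_that("inference validates alignment and ranges", {
  expect_error(infer_hsc_reliability(c(1, 0), c(1, 0), c(1, 0), c(1, 0, 0),
                                     times = c(0, 2)), "misaligned")
  expect_error(infer_hsc_reliability(c(1, 1.2), c(1, 0), c(1, 0), c(1, 0),
                                     times = c(0, 2)), "outside")
})
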