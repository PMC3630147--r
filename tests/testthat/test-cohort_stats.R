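test_that("power-law fits are exact on clean data and scale-equivariant", {
  x <- seq(5, 60, by = 2.5)
  f <- fit_power_law(x, 0.01 * x^1.5)
  expect_equal(coef(f), c(a = 0.01, b = 1.5), tolerance = 1e-8)
  f2 <- fit_power_law(3 * x, 0.01 * (3 * x)^1.5)
  expect_equal(f2$b, f$b, tolerance = 1e-8)
  expect_error(fit_power_law(x, -x), "positive")
  expect_error(fit_power_law(rep(2, 6), rep(3, 6)), "degenerate")
})

test_that("the exponent survives multiplicative lognormal noise at cohort size", {
  bhat <- vapply(1:50, function(s) {
    set.seed(s)
    x <- runif(38, 10, 60)
    y <- 0.01 * x * exp(rnorm(38, 0, 0.2))
    fit_power_law(x, y)$b
  }, 0)
  expect_lt(abs(median(bhat) - 1), 0.3)
})

test_that("half-life transforms flip the sign of the tendency", {
  set.seed(7)
  L <- runif(38, 10, 60)
  beta <- 0.005 * L * exp(rnorm(38, 0, 0.1))
  up <- fit_power_law(L, beta)
  down <- fit_power_law(L, log(2) / beta)
  expect_gt(up$b, 0)
  expect_lt(down$b, 0)
  expect_equal(down$b, -up$b, tolerance = 0.2)
})

test_that("well-separated blobs cluster perfectly with significant contrasts", {
  set.seed(1)
  cl <- cluster_lifespan_pairs(
    c(rnorm(12, 15, 1), rnorm(12, 35, 1), rnorm(12, 55, 1)),
    c(rnorm(12, 0.05, 0.005), rnorm(12, 0.15, 0.005), rnorm(12, 0.3, 0.005)))
  expect_equal(cl$labels, rep(1:3, each = 12))
  expect_true(all(cl$pairwise_p < 0.05))
  expect_length(cl$pairwise_p, 3)
  expect_equal(cl$confirmatory_agreement, 1)
})

test_that("clustering is invariant to affine rescaling of either column", {
  set.seed(2)
  L <- c(rnorm(10, 15, 2), rnorm(10, 40, 2), rnorm(10, 58, 2))
  v <- c(rnorm(10, 1, 0.2), rnorm(10, 3, 0.2), rnorm(10, 6, 0.2))
  a <- cluster_lifespan_pairs(L, v)
  b <- cluster_lifespan_pairs(10 * L + 3, 0.01 * v - 5)
  expect_identical(a$labels, b$labels)
  expect_error(cluster_lifespan_pairs(L[1:6], v[1:6], k = 3), "need >= 3k")
})

test_that("the median Hurst test behaves under shift and symmetry", {
  expect_lt(median_hurst_test(rep(0.3, 38))$p, 1e-4)
  sym <- 0.5 + c(-0.1, 0.1, -0.05, 0.05, -0.2, 0.2, -0.15, 0.15)
  expect_gt(median_hurst_test(sym)$p, 0.5)
  expect_error(median_hurst_test(c(0.4, 0.4, 0.4)), ">= 6")
  expect_error(median_hurst_test(rep(0.5, 10)), "degenerate")
})

test_that("Gumbel machinery is exact under location shifts and recovers parameters", {
  set.seed(11)
  L <- rgumbel(400, 30, 8)
  f1 <- fit_gumbel_lifespans(L, n_boot = 50, seed = 1)
  f2 <- fit_gumbel_lifespans(L + 7, n_boot = 50, seed = 1)
  expect_equal(f2$location - f1$location, 7, tolerance = 1e-4)
  expect_equal(f2$scale, f1$scale, tolerance = 1e-4)
  expect_lt(abs(f1$location - 30), 1.5)
  expect_lt(abs(f1$scale - 8), 1.5)
  expect_error(fit_gumbel_lifespans(1:5), ">= 8")
})

test_that("the Gumbel distribution functions are mutually consistent", {
  q <- qgumbel(c(0.1, 0.5, 0.9), 30, 8)
  expect_equal(pgumbel(q, 30, 8), c(0.1, 0.5, 0.9), tolerance = 1e-12)
  expect_equal(integrate(dgumbel, -50, 200, location = 30, scale = 8)$value,
               1, tolerance = 1e-6)
})

test_that("time-to-failure scales as a power of proliferative capacity", {
  set.seed(5)
  L <- runif(20, 15, 55)
  peaks <- (L / 6)^2          # L = 6 * peak^(1/2) by construction
  clones <- lapply(seq_along(L), function(i)
    gen_clone(L = L[i], peak_height = peaks[i],
              noise_cv = 0, lineage_weights = NULL, seed = i,
              clone_id = paste0("c", i)))
  batch <- kinetic_batch(clones)
  fit <- fit_ttf_power_law(batch, capacity = "peak")
  expect_lt(abs(fit$b - 0.5), 0.1)
  # permuted capacities carry no signal
  caps <- attr(fit, "capacity")
  set.seed(9)
  perm <- fit_power_law(sample(caps), L)
  expect_gt(perm$p_b, 0.05)
  expect_lt(abs(perm$b), abs(fit$b))
  expect_error(fit_ttf_power_law(kinetic_batch(clones[1])), ">= 4")
})

test_that("analytic dissipation recovers the family shape from a clean profile", {
  for (i in 1:5) {
    L <- c(20, 30, 40, 50, 60)[i]
    kk <- 0.4 * i
    cl <- gen_hazard_clone(L = L, k_shape = kk, noise_cv = 0, seed = i,
                           lineage_weights = NULL)
    d <- analytic_dissipation(reliability_profile(cl), L = L)
    expect_equal(d$k, kk, tolerance = 1e-9)
    expect_equal(d$beta_bar, kk * log((L - 2) / 4) / (L - 6), tolerance = 1e-9)
    expect_equal(d$halflife * d$beta_bar, log(2), tolerance = 1e-12)
  }
})
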