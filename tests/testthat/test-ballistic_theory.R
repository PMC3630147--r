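pd <- make_family(density_family("power_decay", lifespan = 40, exponent = 3))
tw <- make_family(density_family("trend_work", lifespan = 40))

test_that("closed forms evaluate as derived for both families", {
  expect_equal(pd$lambda_fn(0), 0.1)
  expect_equal(pd$beta_fn(20), 0.15)
  expect_equal(pd$c_L, 4)
  expect_equal(tw$lambda_fn(0), 0.05)
  expect_equal(tw$lambda_fn(20), 0)
  expect_equal(tw$c_L, 1)
  for (cv in list(pd, tw)) {
    expect_equal(cv$R_fn(0), 1)
    expect_equal(cv$R_fn(cv$lifespan), 0)
  }
})

test_that("family specs are validated", {
  expect_error(density_family("power_decay", lifespan = -1), "lifespan")
  expect_error(density_family("power_decay", lifespan = 40, exponent = 0), "exponent")
  expect_error(density_family("trend_work", lifespan = 40, peak_time = 40), "peak_time")
})

test_that("universal hazard identities hold numerically at random times", {
  set.seed(1)
  for (cv in list(pd, tw, make_family(density_family("power_decay", 25, exponent = 1.4)))) {
    L <- cv$lifespan
    t <- stats::runif(100, 0.01 * L, 0.97 * L)
    if (length(cv$nonsmooth) > 0)
      t <- t[abs(t - cv$nonsmooth) > 0.02 * L]
    # lambda = f / R
    expect_equal(cv$lambda_fn(t), cv$f_fn(t) / cv$R_fn(t), tolerance = 1e-10)
    # lambda = -(log R)' by centered differences
    h <- 1e-6 * L
    dlogR <- -(log(cv$R_fn(t + h)) - log(cv$R_fn(t - h))) / (2 * h)
    expect_equal(cv$lambda_fn(t), dlogR, tolerance = 1e-5)
    # lambda' = lambda (lambda - beta), against numeric differentiation
    slope <- failure_rate_slope(cv, t)
    num <- (cv$lambda_fn(t + h) - cv$lambda_fn(t - h)) / (2 * h)
    expect_equal(slope, num, tolerance = 1e-6)
    # Langevin split sums back to the slope
    lf <- langevin_form(cv, t)
    expect_equal(lf$drift + lf$msv, slope, tolerance = 1e-12)
  }
})

test_that("the slope flags non-smooth points and vanishes at the balance point", {
  expect_error(failure_rate_slope(tw, 20), "non-smooth")
  expect_equal(failure_rate_slope(pd, 20), 0.2 * (0.2 - 0.15))
  # margin at t0 is zero by definition
  expect_equal(imperfect_repair_margin(pd, pd$t0), 1 / 40)
  expect_lt(imperfect_repair_margin(tw, 10), 0)   # early repair excess
  expect_gt(imperfect_repair_margin(tw, 30), 0)
  expect_equal(langevin_form(tw, 20)$drift, 0)
  expect_equal(langevin_form(tw, 20)$msv, 0)
})

test_that("initial damage load is positive and decreasing in lifespan", {
  expect_equal(initial_damage_load(make_family(density_family("power_decay", 10, exponent = 3))), 0.4)
  expect_equal(initial_damage_load(pd), 0.1)
  expect_equal(initial_damage_load(tw), 0.05)
  for (L in c(10, 20, 40, 60)) {
    cv <- make_family(density_family("power_decay", L, exponent = 3))
    expect_equal(initial_damage_load(cv) * L, 4)    # family constant k + 1
    cw <- make_family(density_family("trend_work", L))
    expect_equal(initial_damage_load(cw) * L, 2)
  }
})

test_that("(L - t) * lambda converges to the asymptotic constant and lambda diverges", {
  expect_equal(as.numeric(asymptotic_constant(pd)), 4)
  expect_equal(as.numeric(asymptotic_constant(tw)), 1)
  for (cv in list(pd, tw)) {
    eps <- cv$c_L * 1e-4
    expect_gt(cv$lambda_fn(cv$lifespan - eps), 1e3)
  }
})

test_that("mean dissipation matches its closed form and is monotone in the shape", {
  bb <- mean_dissipation(pd, 2, 36)
  expect_equal(as.numeric(bb), (3 / 34) * log(38 / 4), tolerance = 1e-9)
  # frozen constant-beta toy: the window average equals the constant
  toy <- structure(list(beta_fn = function(t) rep(0.15, length(t)),
                        t_star = 0, lifespan = 40, nonsmooth = numeric(0)),
                   class = "theory_curves")
  expect_equal(as.numeric(mean_dissipation(toy, 2, 36)), 0.15, tolerance = 1e-10)
  b3 <- mean_dissipation(make_family(density_family("power_decay", 40, exponent = 3)), 2, 36)
  b5 <- mean_dissipation(make_family(density_family("power_decay", 40, exponent = 5)), 2, 36)
  expect_gt(as.numeric(b5), as.numeric(b3))
  expect_error(mean_dissipation(pd, 10, 50), "lower < upper")
  # automatic window mirrors the (0,2) truncation at 2-month sampling
  expect_equal(attr(mean_dissipation(pd), "bounds"), c(lower = 2, upper = 36))
})

test_that("the discrete profile of a noise-free ballistic kinetic matches the trend_work forms", {
  L <- 40
  k <- gen_clone(L = L, peak_height = 30, noise_cv = 0, dt = L / 1e4,
                 lineage_weights = NULL, seed = 1)
  p <- reliability_profile(k)
  tt <- p$times
  expect_equal(p$failure_prob, tw$R_fn(tt) * 0 + (1 - tw$R_fn(tt)), tolerance = 1e-3)
  tl <- tt[-length(tt)]
  keep <- tw$R_fn(tl) > 0.05 & abs(tl - L / 2) > 0.01 * L
  expect_lt(max(abs(p$failure_rate[keep] - tw$lambda_fn(tl[keep]))), 1e-3)
})
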