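#' Generate one synthetic clonal kinetic from a ballistic trend
#'
#' Builds a ballistic (rise-then-fall) chimerism trend
#' `y(t) = c t (L - t)`, scaled so the peak reaches `peak_height`, sampled
#' every `dt` months from 0 to the lifespan `L`, with multiplicative noise
#' `y * (1 + eps)` clipped into `[0, 100]`. Three noise structures:
#' \describe{
#'   \item{`iid`}{`eps_k` iid `N(0, noise_cv)` — pure measurement noise
#'     (the default);}
#'   \item{`ou`}{`eps_k` follows a discrete Ornstein-Uhlenbeck process with
#'     dissipation rate `noise_beta` and stationary standard deviation
#'     `noise_cv`;}
#'   \item{`fgn`}{`eps_k = noise_cv *` fractional Gaussian noise with
#'     Hurst exponent `noise_H` — prescribed long-range memory.}
#' }
#' Lineage series are Dirichlet-perturbed fractions of the total: at each
#' time the (T, B, My) weights are drawn around `lineage_weights` with
#' concentration `lineage_conc` (larger = tighter; `Inf` = exact weights,
#' making the lineage sum equal the total).
#'
#' For cohort generation with an imposed lifespan-dissipation structure
#' see [gen_hazard_clone()], which prescribes the failure-rate process
#' itself.
#'
#' @param L Lifespan in months (`> 2 dt`).
#' @param peak_height Peak chimerism in percent, in (0, 100].
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param dt Sampling interval (months, default 2).
#' @param lineage_weights Named base fractions for T/B/My (summing to 1),
#'   or `NULL` for no lineages.
#' @param seed Integer seed; the generator is a pure function of it.
#' @param noise_mode `"iid"`, `"ou"` or `"fgn"`.
#' @param noise_beta OU dissipation of the noise (1/month; `ou` mode).
#' @param noise_H Hurst exponent of the noise (`fgn` mode).
#' @param lineage_conc Dirichlet concentration (default 50; `Inf` exact).
#' @param clone_id Label for the clone.
#' @return A [clonal_kinetic()].
#' @examples
#' gen_clone(L = 40, peak_height = 30, noise_cv = 0, seed = 1)
#' @export
gen_clone <- function(L, peak_height = 30, noise_cv = 0.1, dt = 2,
                      lineage_weights = c(T = 0.3, B = 0.5, My = 0.2),
                      seed = 1L, noise_mode = c("iid", "ou", "fgn"),
                      noise_beta = 0.2, noise_H = 0.5,
                      lineage_conc = 50, clone_id = "synthetic") {
  noise_mode <- match.arg(noise_mode)
  if (L <= 2 * dt) stop("require L > 2 * dt", call. = FALSE)
  if (peak_height <= 0 || peak_height > 100)
    stop("peak_height must lie in (0, 100]", call. = FALSE)
  if (noise_cv < 0 || noise_cv >= 1)
    stop("noise_cv must lie in [0, 1)", call. = FALSE)
  tt <- seq(0, L, by = dt)
  trend <- (4 * peak_height / L^2) * tt * (L - tt)
  n <- length(tt)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  eps <- gen_noise(n, noise_mode, noise_cv, dt, noise_beta, noise_H, seed)
  y <- pmin(100, pmax(0, trend * (1 + eps)))
  lineages <- gen_lineages(y, lineage_weights, lineage_conc)
  clonal_kinetic(clone_id, tt, y, lineages = lineages, lifespan = L)
}

gen_noise <- function(n, noise_mode, noise_cv, dt, noise_beta, noise_H, seed) {
  if (noise_cv == 0) return(numeric(n))
  switch(noise_mode,
    iid = stats::rnorm(n, 0, noise_cv),
    ou = {
      rho <- 1 - noise_beta * dt
      if (rho <= 0 || rho >= 1)
        stop("require 0 < noise_beta * dt < 1 for OU noise", call. = FALSE)
      e <- numeric(n)
      e[1] <- stats::rnorm(1, 0, noise_cv)
      innov_sd <- noise_cv * sqrt(1 - rho^2)
      z <- stats::rnorm(n - 1)
      for (k in seq_len(n - 1)) e[k + 1] <- rho * e[k] + innov_sd * z[k]
      e
    },
    fgn = noise_cv * as.numeric(gen_fgn(n, noise_H, seed = seed + 1L)))
}

gen_lineages <- function(y, lineage_weights, lineage_conc) {
  if (is.null(lineage_weights)) return(NULL)
  n <- length(y)
  w0 <- lineage_weights / sum(lineage_weights)
  W <- if (is.infinite(lineage_conc)) {
    matrix(w0, nrow = n, ncol = length(w0), byrow = TRUE)
  } else {
    t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(w0), shape = lineage_conc * w0)
      g / sum(g)
    }, numeric(length(w0))))
  }
  lineages <- lapply(seq_along(w0), function(j) y * W[, j])
  names(lineages) <- names(w0)
  lineages
}

#' Generate a clonal kinetic with a prescribed failure-rate process
#'
#' Prescribes the clone's discrete failure-rate series directly and inverts
#' it into a chimerism kinetic, so the derived reliability profile of the
#' generated clone reproduces the prescribed hazard exactly. The hazard is
#' the discrete hazard of the `power_decay` family core,
#' `R(t) = (1 - t/L)^{k+1}`, times multiplicative fluctuations `1 + e_k`
#' where `e_k` is a stationary Ornstein-Uhlenbeck process with dissipation
#' rate `beta` and stationary standard deviation `noise_cv` (or fractional
#' Gaussian noise with exponent `noise_H` under `noise_mode = "fgn"`). The
#' final interval's hazard is pinned at `1/dt` so reliability reaches zero
#' at the lifespan.
#'
#' Inversion: with failure probabilities `F_k` accumulated from the hazard,
#' the kinetic rises as `y = 2 p F` until `F` first reaches 1/2 and falls
#' with increments `-2 p dF` afterwards (`p` = peak height) — the exact
#' inverse of the total-variation work normalization, up to a small
#' non-negative terminal remnant when `F` skips over 1/2 between samples.
#'
#' @param L Lifespan (months).
#' @param k_shape Family shape exponent `k > 0`.
#' @param peak_height Peak chimerism (percent).
#' @param noise_cv Stationary relative amplitude of the hazard
#'   fluctuations.
#' @param dt Sampling interval (months).
#' @param beta OU dissipation rate of the fluctuations (1/month),
#'   `beta * dt < 1`.
#' @param seed Integer seed.
#' @param noise_mode `"ou"` (default) or `"fgn"`.
#' @param noise_H Hurst exponent for `"fgn"` fluctuations.
#' @param lineage_weights,lineage_conc As in [gen_clone()].
#' @param clone_id Label.
#' @return A [clonal_kinetic()] whose [reliability_profile()] failure rate
#'   equals the prescribed hazard to machine precision.
#' @export
gen_hazard_clone <- function(L, k_shape, peak_height = 30, noise_cv = 0.1,
                             dt = 2, beta = 0.2, seed = 1L,
                             noise_mode = c("ou", "fgn"), noise_H = 0.5,
                             lineage_weights = c(T = 0.3, B = 0.5, My = 0.2),
                             lineage_conc = 50, clone_id = "synthetic") {
  noise_mode <- match.arg(noise_mode)
  if (L <= 3 * dt) stop("require L > 3 * dt", call. = FALSE)
  if (k_shape <= 0) stop("k_shape must be > 0", call. = FALSE)
  tt <- seq(0, L, by = dt)
  N <- length(tt) - 1L
  R_det <- (1 - tt / L)^(k_shape + 1)
  lam_det <- (R_det[-(N + 1)] - R_det[-1]) / (dt * R_det[-(N + 1)])
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  e <- gen_noise(N, if (noise_mode == "ou") "ou" else "fgn",
                 noise_cv, dt, beta, noise_H, seed)
  lam <- pmin(pmax(lam_det * (1 + e), 1e-4), 0.995 / dt)
  lam[N] <- 1 / dt   # extinction: R(L) = 0
  R <- cumprod(c(1, 1 - lam * dt))
  F <- 1 - R
  p <- which(F >= 0.5)[1]
  s <- ifelse(seq_len(N) < p, 1, -1)
  y <- cumsum(c(0, s * 2 * peak_height * diff(F)))
  y <- pmin(100, pmax(0, y))
  lineages <- gen_lineages(y, lineage_weights, lineage_conc)
  clonal_kinetic(clone_id, tt, y, lineages = lineages, lifespan = L)
}

#' Cohort generation specification
#'
#' Parameters of a synthetic cohort emulating a clonal repopulation study:
#' `n_clones` single-HSC kinetics sampled every `dt` months with lifespans
#' spread over `lifespan_range`, and an imposed power law
#' `beta_bar(L) = a * L^b` linking each clone's mean failure-dissipation
#' rate to its lifespan. Per clone the `power_decay` shape exponent `k` is
#' solved so the analytic mean dissipation over the pre-extinction window
#' equals the law exactly, and the clone is generated by
#' [gen_hazard_clone()] with hazard fluctuations that revert at the same
#' rate.
#'
#' @param n_clones Number of clones (default 38).
#' @param lifespan_range Months (default `c(10, 60)`).
#' @param lifespan_law `"uniform"` or `"gumbel"` (location 30, scale 8,
#'   resampled into range).
#' @param dt Sampling interval (default 2 months).
#' @param noise_cv Relative amplitude of hazard fluctuations (default 0.1).
#' @param beta_law `c(a, b)` of the imposed dissipation power law
#'   (default `a = 0.005`, `b = 1`: dissipation rates of 0.05-0.3 per
#'   month, half-lives of roughly 2-14 months across the lifespan range).
#' @param noise_mode `"ou"` (default; fluctuations revert at
#'   `beta_bar(L)`) or `"fgn"` (fluctuations with Hurst exponent
#'   `H(L)` from `hurst_law`).
#' @param hurst_law For `noise_mode = "fgn"`: `c(intercept, slope)` of the
#'   per-clone target `H(L) = intercept + slope * L` (default
#'   `c(0.5, -0.004)`, anti-persistence deepening with lifespan).
#' @param peak_range Percent range for peak heights (default `c(20, 60)`).
#' @param lineage_weights,lineage_conc See [gen_clone()].
#' @param seed Cohort seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_clones = 38L, lifespan_range = c(10, 60),
                        lifespan_law = c("uniform", "gumbel"), dt = 2,
                        noise_cv = 0.1, beta_law = c(a = 0.005, b = 1),
                        noise_mode = c("ou", "fgn"),
                        hurst_law = c(0.5, -0.004),
                        peak_range = c(20, 60),
                        lineage_weights = c(T = 0.3, B = 0.5, My = 0.2),
                        lineage_conc = 50, seed = 1L) {
  lifespan_law <- match.arg(lifespan_law)
  noise_mode <- match.arg(noise_mode)
  if (n_clones < 1) stop("n_clones must be >= 1", call. = FALSE)
  if (noise_cv < 0 || noise_cv >= 1) stop("noise_cv must lie in [0, 1)",
                                          call. = FALSE)
  if (lifespan_range[1] <= 4 * dt)
    stop("lifespan_range too low for the sampling interval", call. = FALSE)
  structure(list(n_clones = as.integer(n_clones),
                 lifespan_range = lifespan_range,
                 lifespan_law = lifespan_law, dt = dt, noise_cv = noise_cv,
                 beta_law = c(a = unname(beta_law[1]), b = unname(beta_law[2])),
                 noise_mode = noise_mode, hurst_law = hurst_law,
                 peak_range = peak_range, lineage_weights = lineage_weights,
                 lineage_conc = lineage_conc, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d clones, lifespans %g-%g months (%s), dt = %g, %s noise cv = %g\n",
              x$n_clones, x$lifespan_range[1], x$lifespan_range[2],
              x$lifespan_law, x$dt, x$noise_mode, x$noise_cv))
  cat(sprintf("  imposed dissipation law: beta_bar(L) = %g * L^%g\n",
              x$beta_law["a"], x$beta_law["b"]))
  invisible(x)
}

#' Shape exponent matching a target mean dissipation
#'
#' For the `power_decay` family the mean dissipation over the
#' pre-extinction window `[dt, L - 2 dt]` is
#' `beta_bar = k * log((L - dt)/(2 dt)) / (L - 3 dt)`; this solves for the
#' shape exponent `k` that realizes a target `beta_bar`.
#'
#' @param beta_bar Target mean dissipation rate (1/month).
#' @param L Lifespan (months).
#' @param dt Sampling interval (months).
#' @return `k > 0`.
#' @export
solve_k_for_beta_bar <- function(beta_bar, L, dt = 2) {
  lo <- dt; hi <- L - 2 * dt
  fac <- log((L - lo) / (L - hi)) / (hi - lo)
  k <- beta_bar / fac
  if (!is.finite(k) || k <= 0)
    stop("infeasible beta_bar for lifespan ", L, call. = FALSE)
  k
}

#' Generate a synthetic cohort with imposed lifespan-dissipation structure
#'
#' Draws `n_clones` lifespans, builds one kinetic per clone via
#' [gen_hazard_clone()], and emits a ground-truth table alongside the
#' batch so recovery tests never have to reverse-engineer the generator:
#' per clone the lifespan `L`, the shape exponent `k` (solved so the
#' analytic mean dissipation equals `beta_bar_true = a * L^b` exactly),
#' that `beta_bar_true`, its half-life `log(2)/beta_bar_true`, and (under
#' fGn noise) the target Hurst exponent.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `batch` (a [kinetic_batch()]) and `truth` (a data
#'   frame with columns `clone_id`, `L`, `k`, `beta_bar_true`,
#'   `halflife_true`, `H_target`).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(spec$seed)
  n <- spec$n_clones
  rng <- spec$lifespan_range
  L <- if (spec$lifespan_law == "uniform") {
    stats::runif(n, rng[1], rng[2])
  } else {
    x <- rgumbel(4 * n, location = 30, scale = 8)
    x <- x[x >= rng[1] & x <= rng[2]]
    while (length(x) < n) x <- c(x, rgumbel(4 * n, 30, 8))
    x[seq_len(n)]
  }
  peaks <- stats::runif(n, spec$peak_range[1], spec$peak_range[2])
  clone_seeds <- sample.int(2^30, n)
  a <- spec$beta_law["a"]; b <- spec$beta_law["b"]
  beta_true <- unname(a * L^b)
  if (spec$noise_mode == "ou" && any(beta_true * spec$dt >= 1))
    stop("infeasible beta_law: beta_bar * dt >= 1 at the upper lifespans",
         call. = FALSE)
  k_true <- vapply(seq_len(n),
                   function(i) solve_k_for_beta_bar(beta_true[i], L[i], spec$dt),
                   0)
  H_target <- if (spec$noise_mode == "fgn") {
    pmin(0.95, pmax(0.05, spec$hurst_law[1] + spec$hurst_law[2] * L))
  } else rep(NA_real_, n)
  clones <- lapply(seq_len(n), function(i) {
    gen_hazard_clone(L = L[i], k_shape = k_true[i], peak_height = peaks[i],
                     noise_cv = spec$noise_cv, dt = spec$dt,
                     beta = beta_true[i], seed = clone_seeds[i],
                     noise_mode = spec$noise_mode, noise_H = H_target[i],
                     lineage_weights = spec$lineage_weights,
                     lineage_conc = spec$lineage_conc,
                     clone_id = sprintf("clone%02d", i))
  })
  truth <- data.frame(clone_id = sprintf("clone%02d", seq_len(n)),
                      L = L, k = k_true, beta_bar_true = beta_true,
                      halflife_true = log(2) / beta_true,
                      H_target = H_target, stringsAsFactors = FALSE)
  list(batch = kinetic_batch(clones,
                             provenance = sprintf("gen_cohort seed %d", spec$seed)),
       truth = truth)
}

#' Fractional Gaussian noise
#'
#' Simulates unit-variance fractional Gaussian noise with Hurst exponent
#' `H` by circulant embedding of the fGn autocovariance
#' `gamma(h) = (|h+1|^{2H} - 2|h|^{2H} + |h-1|^{2H}) / 2` (Davies-Harte);
#' if the embedding is not non-negative definite the exact Hosking
#' (Durbin-Levinson) recursion is used instead, with the fallback recorded
#' in attribute `"method"`.
#'
#' @param n Series length (powers of 2 embed most efficiently).
#' @param H Hurst exponent in (0, 1); `H = 0.5` is white noise.
#' @param seed Integer seed; same seed, same series.
#' @return Numeric series of length `n` with attribute `"method"`.
#' @export
gen_fgn <- function(n, H, seed = 1L) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  g <- fgn_autocov(0:(n - 1), H)
  M <- 2L * (n - 1L)
  circ <- c(g, g[(n - 1):2])
  ev <- Re(stats::fft(circ))
  if (min(ev) >= -1e-9) {
    ev[ev < 0] <- 0
    z <- complex(real = stats::rnorm(M), imaginary = stats::rnorm(M))
    x <- Re(stats::fft(sqrt(ev) * z)) / sqrt(M)
    out <- x[seq_len(n)]
    attr(out, "method") <- "circulant"
  } else {
    out <- fgn_hosking(n, H)
    attr(out, "method") <- "hosking"
  }
  out
}

fgn_autocov <- function(h, H) {
  h <- abs(h)
  0.5 * (abs(h + 1)^(2 * H) - 2 * h^(2 * H) + abs(h - 1)^(2 * H))
}

# exact sequential simulation via Durbin-Levinson
fgn_hosking <- function(n, H) {
  g <- fgn_autocov(0:(n - 1), H)
  x <- numeric(n)
  phi <- numeric(n)
  x[1] <- stats::rnorm(1)
  v <- 1
  for (k in 1:(n - 1)) {
    if (k == 1) {
      phi[1] <- g[2]
    } else {
      prev <- phi[1:(k - 1)]
      rk <- (g[k + 1] - sum(prev * g[k:2])) / v
      phi[k] <- rk
      phi[1:(k - 1)] <- prev - rk * rev(prev)
    }
    v <- v * (1 - phi[k]^2)
    m <- sum(phi[1:k] * x[k:1])
    x[k + 1] <- m + sqrt(v) * stats::rnorm(1)
  }
  x
}
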