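#' Deterministic failure-rate family specification
#'
#' The noise-free ("ballistic") core of a clonal repopulation kinetic induces
#' closed-form reliability and failure-rate curves over the clone's lifespan
#' `L`. Two concrete families are provided:
#' \describe{
#'   \item{`power_decay`}{failure density `f(t) = ((k+1)/L) (1 - t/L)^k`
#'     with shape exponent `k > 0`: reliability `R(t) = (1 - t/L)^{k+1}`,
#'     hazard `lambda(t) = (k+1)/(L - t)`, dissipation rate
#'     `beta(t) = -f'/f = k/(L - t) > 0` throughout — the default theory
#'     family, with strictly positive dissipation and imperfect repair
#'     (`lambda > beta`) over the whole lifespan.}
#'   \item{`trend_work`}{curves induced by the symmetric ballistic trend
#'     `y(t) = c t (L - t)` under the total-variation work convention, the
#'     family matched by the discrete profile of a noise-free generated
#'     kinetic: `F(t) = 2 t (L - t) / L^2` for `t <= L/2` and
#'     `1 - 2 t (L - t)/L^2` beyond; piecewise `lambda = f/R`; the peak
#'     `t = L/2` is a non-smooth point.}
#' }
#'
#' @param family `"power_decay"` or `"trend_work"`.
#' @param lifespan Clone lifespan `L` in months, `> 0`.
#' @param exponent Shape exponent `k > 0` (`power_decay` only; default 3).
#' @param peak_height,peak_time Trend parameters in percent / months
#'   (`trend_work` only; cosmetic — the induced normalized curves depend
#'   only on `L`).
#' @return An object of class `"density_family"`.
#' @export
density_family <- function(family = c("power_decay", "trend_work"),
                           lifespan, exponent = 3,
                           peak_height = 30, peak_time = lifespan / 2) {
  family <- match.arg(family)
  if (!is.numeric(lifespan) || lifespan <= 0)
    stop("lifespan must be > 0", call. = FALSE)
  if (family == "power_decay" && (!is.numeric(exponent) || exponent <= 0))
    stop("exponent k must be > 0", call. = FALSE)
  if (family == "trend_work" &&
      (peak_time <= 0 || peak_time >= lifespan || peak_height <= 0))
    stop("peak_time must lie in (0, L) and peak_height > 0", call. = FALSE)
  structure(list(family = family, lifespan = lifespan,
                 exponent = if (family == "power_decay") exponent else NA_real_,
                 trend = c(peak_height = peak_height, peak_time = peak_time)),
            class = "density_family")
}

#' Closed-form theory curves for a ballistic failure-rate family
#'
#' Materializes a [density_family()] into its theory curves: the hazard
#' `lambda(t)`, the dissipation rate `beta(t) = -f'(t)/f(t)` (the restoring
#' "frictional force" that pulls the hazard back toward its mean,
#' interpreted as population-level repair activity), the reliability and
#' failure density, together with the scalar summaries
#' \itemize{
#'   \item `lambda0` — the initial damage load `lambda(0) > 0`, a function
#'     of the clone parameters only;
#'   \item `t0` — the balance point where `lambda = beta` (repair exactly
#'     offsets failure generation);
#'   \item `t_star` — the onset of strict increase of `lambda`;
#'   \item `c_L` — the asymptotic constant `lim (L - t) lambda(t)` as
#'     `t -> L`: the hazard always diverges like `c_L / (L - t)` at the
#'     lifespan.
#' }
#'
#' @param spec A [density_family()].
#' @return An object of class `"theory_curves"` with function fields
#'   `lambda_fn`, `beta_fn`, `R_fn`, `f_fn` and scalars `lambda0`, `t0`,
#'   `t_star`, `c_L`, plus the originating `spec`.
#' @examples
#' cv <- make_family(density_family("power_decay", lifespan = 40, exponent = 3))
#' cv$lambda_fn(0)   # 0.1 = (k+1)/L
#' cv$c_L            # 4   = k+1
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "density_family"))
  L <- spec$lifespan
  if (spec$family == "power_decay") {
    k <- spec$exponent
    curves <- list(
      lambda_fn = function(t) (k + 1) / (L - t),
      beta_fn   = function(t) k / (L - t),
      R_fn      = function(t) (1 - t / L)^(k + 1),
      f_fn      = function(t) ((k + 1) / L) * (1 - t / L)^k,
      lambda0 = (k + 1) / L, t0 = 0, t_star = 0, c_L = k + 1,
      nonsmooth = numeric(0))
  } else {
    # trend_work: induced by y = c t (L - t) under |rate| work
    F_fn <- function(t) ifelse(t <= L / 2,
                               2 * t * (L - t) / L^2,
                               1 - 2 * t * (L - t) / L^2)
    f_fn <- function(t) ifelse(t <= L / 2,
                               2 * (L - 2 * t) / L^2,
                               2 * (2 * t - L) / L^2)
    R_fn <- function(t) 1 - F_fn(t)
    curves <- list(
      lambda_fn = function(t) f_fn(t) / R_fn(t),
      # -f'/f on each smooth piece; f' = -4/L^2 before the peak, +4/L^2 after
      beta_fn   = function(t) ifelse(t < L / 2,
                                     2 / (L - 2 * t),
                                     -2 / (2 * t - L)),
      R_fn = R_fn, f_fn = f_fn,
      lambda0 = 2 / L, t0 = L / 2, t_star = L / 2, c_L = 1,
      nonsmooth = L / 2)
  }
  structure(c(curves, list(spec = spec, lifespan = L)),
            class = "theory_curves")
}

#' @export
print.theory_curves <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("Theory curves [%s]: L = %.4g months", sp$family, x$lifespan))
  if (sp$family == "power_decay") cat(sprintf(", k = %.4g", sp$exponent))
  cat("\n")
  cat(sprintf("  initial damage load lambda(0) = %.6g /month\n", x$lambda0))
  cat(sprintf("  balance point t0 = %.4g, strict-increase onset t* = %.4g months\n",
              x$t0, x$t_star))
  cat(sprintf("  asymptotic constant c_L = %.6g  [lambda ~ c_L/(L - t)]\n", x$c_L))
  invisible(x)
}

#' @export
plot.theory_curves <- function(x, n = 400, ...) {
  L <- x$lifespan
  t <- seq(0, L * (1 - 1e-3), length.out = n)
  plot(t, x$lambda_fn(t), type = "l", log = "y", xlab = "time (months)",
       ylab = "rate (1/month)", main = sprintf("%s family", x$spec$family), ...)
  b <- x$beta_fn(t)
  ok <- b > 0
  graphics::lines(t[ok], b[ok], lty = 2)
  graphics::legend("topleft", legend = c(expression(lambda(t)),
                                         expression(beta(t) > 0)),
                   lty = 1:2, bty = "n")
  invisible(x)
}

check_domain <- function(curves, t) {
  if (any(t < 0 | t >= curves$lifespan))
    stop("t must lie in [0, L)", call. = FALSE)
  if (length(curves$nonsmooth) > 0 &&
      any(abs(outer(t, curves$nonsmooth, `-`)) < 1e-12))
    stop("t is a non-smooth point of this family (trend peak)", call. = FALSE)
  invisible(TRUE)
}

#' Slope of the deterministic failure rate
#'
#' The hazard of any ballistic family obeys the Riccati-type identity
#' `lambda'(t) = lambda(t) (lambda(t) - beta(t))`: the failure rate grows
#' exactly when failure generation outpaces dissipation.
#'
#' @param curves A [make_family()] result.
#' @param t Time(s) in months, `0 <= t < L`, away from non-smooth points.
#' @return `lambda'(t)`.
#' @export
failure_rate_slope <- function(curves, t) {
  check_domain(curves, t)
  lam <- curves$lambda_fn(t)
  lam * (lam - curves$beta_fn(t))
}

#' Imperfect-repair margin
#'
#' Returns `lambda(t) - beta(t)`, positive precisely when failures are
#' generated faster than they are dissipated ("imperfect repair"). For the
#' `power_decay` family the margin equals `1/(L - t) > 0` throughout the
#' lifespan; for `trend_work` repair exceeds generation before the trend
#' peak (`t < t0`) and the sign flips at the balance point `t0`.
#'
#' @inheritParams failure_rate_slope
#' @return `lambda(t) - beta(t)` (1/month).
#' @export
imperfect_repair_margin <- function(curves, t) {
  if (any(t < 0 | t >= curves$lifespan))
    stop("t must lie in [0, L)", call. = FALSE)
  curves$lambda_fn(t) - curves$beta_fn(t)
}

#' Initial damage load
#'
#' The hazard at clone founding, `lambda(0) = f(0)/R(0) = f(0) > 0`. Within
#' a family at fixed shape it decreases in the lifespan (`lambda(0) * L` is
#' the family constant `k + 1`, resp. 2), so shorter-lived clones start with
#' higher damage loads.
#'
#' @param curves A [make_family()] result.
#' @return `lambda(0)` (1/month).
#' @export
initial_damage_load <- function(curves) curves$lambda0

#' Asymptotic hazard constant near the lifespan
#'
#' Numerically verifies `lim_{t -> L} (L - t) lambda(t) = c_L` by evaluating
#' at `t = L (1 - 10^-j)`, `j = 2..6`, and checking convergence to the
#' family's closed-form constant within `tol`.
#'
#' @param curves A [make_family()] result.
#' @param tol Convergence tolerance (default `1e-4`).
#' @return `c_L`, invisibly carrying attribute `"checked"` with the probe
#'   values.
#' @export
asymptotic_constant <- function(curves, tol = 1e-4) {
  L <- curves$lifespan
  tj <- L * (1 - 10^-(2:6))
  probe <- (L - tj) * curves$lambda_fn(tj)
  if (abs(probe[length(probe)] - curves$c_L) > tol)
    stop(sprintf("(L-t)*lambda(t) does not converge to c_L = %.6g (got %.6g)",
                 curves$c_L, probe[length(probe)]), call. = FALSE)
  structure(curves$c_L, checked = probe)
}

#' Mean dissipation rate over a pre-extinction window
#'
#' Averages the dissipation rate,
#' `beta_bar = (1/(upper - lower)) * integral of beta(t) dt`, by adaptive
#' quadrature. The automatic bounds mirror the `(0, 2)` truncation of
#' discrete failure rates at the sampling interval `dt_sample`:
#' `lower = max(t_star, dt_sample)` and `upper = L - 2 dt_sample`. For the
#' `power_decay` family the closed form is
#' `beta_bar = k * log((L - lower)/(L - upper)) / (upper - lower)`.
#'
#' @param curves A [make_family()] result.
#' @param lower,upper Integration bounds in months, or `NULL` for the
#'   automatic pre-extinction window.
#' @param dt_sample Sampling interval used for the automatic bounds
#'   (default 2 months, the every-other-month schedule).
#' @return `beta_bar` (1/month), with attribute `"bounds"`.
#' @examples
#' cv <- make_family(density_family("power_decay", 40, exponent = 3))
#' mean_dissipation(cv, 2, 36)   # (3/34) log(38/4)
#' @export
mean_dissipation <- function(curves, lower = NULL, upper = NULL,
                             dt_sample = 2) {
  L <- curves$lifespan
  if (is.null(lower)) {
    lower <- max(curves$t_star, dt_sample)
    if (length(curves$nonsmooth) > 0 && any(abs(lower - curves$nonsmooth) < 1e-12))
      lower <- lower + dt_sample   # step off the singular trend peak
  }
  if (is.null(upper)) upper <- L - 2 * dt_sample
  if (!(lower < upper && upper <= L - dt_sample / 1e6))
    stop("require lower < upper <= L", call. = FALSE)
  val <- stats::integrate(curves$beta_fn, lower, upper,
                          rel.tol = 1e-10, subdivisions = 500L)$value
  structure(val / (upper - lower), bounds = c(lower = lower, upper = upper))
}

#' Deterministic Langevin decomposition of the hazard slope
#'
#' Writes `lambda' = -beta * lambda + lambda^2`: a dissipative (frictional)
#' drift term plus a mean-squared-variation analog, the noise-free
#' counterpart of the Langevin form of a mean-reverting failure rate. The
#' two terms always sum to [failure_rate_slope()].
#'
#' @inheritParams failure_rate_slope
#' @return A list with `drift` (`-beta*lambda`), `msv` (`lambda^2`) and
#'   their sum `slope`.
#' @export
langevin_form <- function(curves, t) {
  if (any(t < 0 | t >= curves$lifespan))
    stop("t must lie in [0, L)", call. = FALSE)
  lam <- curves$lambda_fn(t)
  # at a zero of lambda (trend_work peak) both terms vanish even though
  # beta alone is singular there
  drift <- ifelse(lam == 0, 0, -curves$beta_fn(t) * lam)
  list(drift = drift, msv = lam^2, slope = drift + lam^2)
}
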