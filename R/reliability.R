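#' Per-interval instantaneous repopulation rates
#'
#' Approximates the derivative of a chosen chimerism series by successive
#' differences: `r_j = (y_{j+1} - y_j) / (t_{j+1} - t_j)`, in percent per
#' month, one value per sampling interval.
#'
#' @param k A [clonal_kinetic()].
#' @param series Which population to differentiate: `"clone"` (the total
#'   kinetic) or a lineage name `"T"`, `"B"`, `"My"`.
#' @return Numeric vector of length `N - 1`.
#' @export
instantaneous_rates <- function(k, series = "clone") {
  y <- kinetic_series(k, series)
  dt <- diff(k$times)
  if (any(dt <= 0)) stop("zero or negative time step", call. = FALSE)
  diff(y) / dt
}

kinetic_series <- function(k, series) {
  if (series %in% c("clone", "total")) return(k$total)
  if (!is.null(k$lineages) && series %in% names(k$lineages))
    return(k$lineages[[series]])
  stop("series '", series, "' not present in clone '", k$clone_id, "'",
       call. = FALSE)
}

new_reliability_profile <- function(times, rates, work, population,
                                    trunc = c(0L, 0L), clamped = 0L) {
  A <- sum(work)
  if (A <= 0)
    stop("degenerate kinetic: all rates are zero (no realized work)",
         call. = FALSE)
  dt <- diff(times)
  F <- c(0, cumsum(work) / A)
  F[length(F)] <- 1            # guard cumulative rounding
  R <- 1 - F
  f <- work / (A * dt)
  lambda <- f / R[-length(R)]  # left-endpoint reliability
  structure(list(times = times, rates = rates, norm_A = A,
                 reliability = R, failure_prob = F,
                 failure_density = f, failure_rate = lambda,
                 truncation = as.integer(trunc), population = population,
                 clamped = clamped),
            class = "reliability_profile")
}

#' Discrete reliability profile of a clonal kinetic
#'
#' Transforms a repopulation kinetic into its reliability decomposition.
#' The realized repopulation work on each sampling interval is
#' `w_j = |r_j| * dt_j` (total variation of the kinetic; under
#' `work = "squared"`, `r_j^2 * dt_j`), normalized by the total work
#' `A = sum(w_j)`. Then
#' \itemize{
#'   \item failure probability `F(t_1) = 0`,
#'     `F(t_{k+1}) = sum_{j<=k} w_j / A` (reaches 1 at the last time);
#'   \item reliability `R = 1 - F`, non-increasing from 1 to 0;
#'   \item failure density `f_k = w_k / (A * dt_k)` per interval (1/month);
#'   \item failure rate (hazard) `lambda_k = f_k / R(t_k)`, using the
#'     reliability at the interval's left endpoint so all `N - 1` values
#'     are defined.
#' }
#' Under total-variation work the reliability is the normalized remaining
#' repopulation work of the clone, and `R + F = 1` and
#' `sum(f_k * dt_k) = 1` hold exactly.
#'
#' @inheritParams instantaneous_rates
#' @param work Work convention per interval: `"absolute"` (default,
#'   total variation) or `"squared"`.
#' @return An object of class `"reliability_profile"` with fields `times`,
#'   `rates`, `norm_A`, `reliability`, `failure_prob`, `failure_density`,
#'   `failure_rate`, `truncation`, `population`.
#' @examples
#' k <- clonal_kinetic("toy", c(0, 2, 4, 6, 8), c(0, 10, 20, 10, 0))
#' p <- reliability_profile(k)
#' p$failure_prob    # 0 .25 .5 .75 1
#' p$failure_rate    # increases toward extinction
#' @export
reliability_profile <- function(k, series = "clone",
                                work = c("absolute", "squared")) {
  work <- match.arg(work)
  r <- instantaneous_rates(k, series)
  dt <- diff(k$times)
  w <- if (work == "absolute") abs(r) * dt else r^2 * dt
  new_reliability_profile(k$times, r, w, population = series)
}

#' @export
print.reliability_profile <- function(x, ...) {
  cat(sprintf("Reliability profile [%s]: %d time points, %.4g-%.4g months\n",
              x$population, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  total work A = %.6g; truncation (%d,%d)\n",
              x$norm_A, x$truncation[1], x$truncation[2]))
  lam <- x$failure_rate
  cat(sprintf("  failure rate: %.4g (start) -> %.4g (final interval)\n",
              lam[1], lam[length(lam)]))
  if (x$clamped > 0)
    cat(sprintf("  inferred reliability clamped at %d point(s)\n", x$clamped))
  invisible(x)
}

#' @export
as.data.frame.reliability_profile <- function(x, ...) {
  n <- length(x$times)
  data.frame(time_months = x$times,
             rate = c(x$rates, NA),
             R = x$reliability,
             F = x$failure_prob,
             f = c(x$failure_density, NA),
             lambda = c(x$failure_rate, NA),
             population = x$population,
             trunc_m = x$truncation[1],
             trunc_n = x$truncation[2],
             stringsAsFactors = FALSE)
}

#' @export
plot.reliability_profile <- function(x, which = c("R", "lambda"), ...) {
  which <- match.arg(which)
  if (which == "R") {
    plot(x$times, x$reliability, type = "b", xlab = "time (months)",
         ylab = "reliability R(t)", main = paste("Reliability:", x$population), ...)
  } else {
    tl <- x$times[-length(x$times)]
    plot(tl, x$failure_rate, type = "b", xlab = "time (months)",
         ylab = expression(lambda(t) ~ (1/month)),
         main = paste("Failure rate:", x$population), ...)
  }
  invisible(x)
}

#' Truncate a failure-rate series
#'
#' An `(m, n)`-truncated failure-rate kinetic drops `m` elements from the
#' beginning and `n` from the end of the series. The `(0, 2)` truncation is
#' the standard pre-extinction analysis window for 2-month sampling: it
#' removes the terminal divergence of the hazard so the mean-reverting
#' interior can be studied.
#'
#' @param p A `reliability_profile`, or a bare numeric failure-rate vector.
#' @param m,n Non-negative counts of leading / trailing elements to remove;
#'   must satisfy `m + n < length(series)`.
#' @return A list with `times` (left interval endpoints), `failure_rate`
#'   and `truncation = c(m, n)`.
#' @export
truncate_failure_rate <- function(p, m = 0L, n = 2L) {
  if (inherits(p, "reliability_profile")) {
    lam <- p$failure_rate
    tl <- p$times[-length(p$times)]
  } else {
    lam <- as.numeric(p)
    tl <- seq_along(lam) - 1
  }
  m <- as.integer(m); n <- as.integer(n)
  if (m < 0 || n < 0) stop("truncation counts must be non-negative", call. = FALSE)
  if (m + n >= length(lam))
    stop(sprintf("truncation (%d,%d) removes the whole series of length %d",
                 m, n, length(lam)), call. = FALSE)
  idx <- seq.int(m + 1L, length(lam) - n)
  list(times = tl[idx], failure_rate = lam[idx], truncation = c(m, n))
}

#' Infer the HSC-population reliability from a common-cause structure balance
#'
#' The HSC pool is the unobserved common cause of the clone and of every
#' mature lineage. Treating (HSC pool, clone) and (T, B, myeloid) as two
#' parallel reliability structures of the same system, conservation of
#' system structure requires
#' `1 - (1-R_HSC)(1-R_clone) = 1 - (1-R_T)(1-R_B)(1-R_My)` at every time,
#' which is solved pointwise for
#' `R_HSC = 1 - (1-R_T)(1-R_B)(1-R_My) / (1-R_clone)`.
#' The 0/0 case at fully reliable early times (`R_clone = 1`) resolves to
#' `R_HSC = 1`. Noise can push the ratio outside `[0, 1]`; such values are
#' clamped and the clamp count is recorded on the returned profile (never
#' silently).
#'
#' @param R_clone,R_T,R_B,R_My Reliability series on a common time grid,
#'   values in `[0, 1]`; either numeric vectors (with `times` supplied) or
#'   `reliability_profile` objects.
#' @param times Time grid in months (ignored when profiles are passed).
#' @return A `reliability_profile` with `population = "HSC"`: downstream
#'   `F`, `f` and `lambda` are derived from the inferred reliability exactly
#'   as in [reliability_profile()].
#' @export
infer_hsc_reliability <- function(R_clone, R_T, R_B, R_My, times = NULL) {
  grab <- function(x) {
    if (inherits(x, "reliability_profile")) list(R = x$reliability, t = x$times)
    else list(R = as.numeric(x), t = times)
  }
  a <- grab(R_clone); b <- grab(R_T); c_ <- grab(R_B); d <- grab(R_My)
  if (is.null(a$t)) stop("supply `times` or reliability_profile objects",
                         call. = FALSE)
  lens <- c(length(a$R), length(b$R), length(c_$R), length(d$R), length(a$t))
  if (length(unique(lens)) != 1)
    stop("misaligned series lengths", call. = FALSE)
  for (g in list(b, c_, d)) {
    if (!is.null(g$t) && max(abs(g$t - a$t)) > 1e-9)
      stop("misaligned time grids", call. = FALSE)
  }
  allR <- c(a$R, b$R, c_$R, d$R)
  if (any(allR < -1e-9 | allR > 1 + 1e-9))
    stop("reliability values outside [0, 1]", call. = FALSE)
  num <- (1 - b$R) * (1 - c_$R) * (1 - d$R)
  den <- 1 - a$R
  R_hsc <- ifelse(den <= 0, 1, 1 - num / den)
  clamped <- sum(R_hsc < 0 | R_hsc > 1)
  R_hsc <- pmin(1, pmax(0, R_hsc))
  # F, f, lambda derived from the inferred reliability with the same
  # discrete formulas as reliability_profile (R is kept verbatim so the
  # structure balance can be re-checked on the result)
  tt <- a$t
  dt <- diff(tt)
  F <- 1 - R_hsc
  f <- diff(F) / dt
  lambda <- ifelse(R_hsc[-length(R_hsc)] > 0,
                   f / R_hsc[-length(R_hsc)], NA_real_)
  structure(list(times = tt, rates = f, norm_A = 1,
                 reliability = R_hsc, failure_prob = F,
                 failure_density = f, failure_rate = lambda,
                 truncation = c(0L, 0L), population = "HSC",
                 clamped = clamped),
            class = "reliability_profile")
}
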