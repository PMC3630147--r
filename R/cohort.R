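#' Power-law tendency fit
#'
#' Fits `y = a * x^b` to positive data: ordinary least squares in log-log
#' space followed by a direct Levenberg-Marquardt refinement on the
#' original scale. Used for the cohort-level tendencies of the dissipation
#' rate (`beta_bar` increasing with lifespan) and its half-life
#' (decreasing with lifespan). The fit expresses a tendency across
#' independent clones, not a functional dependency.
#'
#' @param x Positive predictor (typically lifespans in months).
#' @param y Positive response (dissipation rates, half-lives, ...).
#' @return An object of class `"power_law_fit"`: `a`, `b`, `aic`
#'   (`n log(RSS/n) + 4`, Gaussian RSS convention on the original scale),
#'   `p_a`, `p_b` (parameter p-values from the nonlinear fit), `n`.
#' @examples
#' f <- fit_power_law(1:20, 0.01 * (1:20)^1.5)
#' coef(f)   # a = 0.01, b = 1.5
#' @export
fit_power_law <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4)
    stop("need >= 4 (x, y) pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive x and y", call. = FALSE)
  if (length(unique(x)) < 2) stop("degenerate predictor", call. = FALSE)
  ll <- stats::lm(log(y) ~ log(x))
  start <- list(a = exp(unname(stats::coef(ll)[1])),
                b = unname(stats::coef(ll)[2]))
  dat <- data.frame(x = x, y = y)
  nlfit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(nlfit)) {
    a <- start$a; b <- start$b
    rss <- sum((y - a * x^b)^2)
    p_a <- p_b <- NA_real_
  } else {
    cf <- summary(nlfit)$coefficients
    a <- cf["a", 1]; b <- cf["b", 1]
    p_a <- cf["a", 4]; p_b <- cf["b", 4]
    rss <- sum(stats::resid(nlfit)^2)
  }
  n <- length(x)
  structure(list(a = a, b = b, aic = n * log(rss / n) + 2 * 2,
                 p_a = p_a, p_b = p_b, n = n),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law tendency: y = %.6g * x^%.6g  (n = %d, AIC = %.4g)\n",
              x$a, x$b, x$n, x$aic))
  cat(sprintf("  parameter p-values: a %.3g, b %.3g\n", x$p_a, x$p_b))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.power_law_fit <- function(object, x, ...) object$a * x^object$b

#' Cluster (lifespan, value) pairs with standardized hierarchical clustering
#'
#' Standardizes both columns (subtract the column mean, divide by the
#' column standard deviation), clusters the standardized points by Ward
#' (\code{ward.D2}) agglomeration on Euclidean distances, cuts at `k`
#' clusters, and compares the value column between every cluster pair with
#' two-sample Wilcoxon rank-sum tests under Bonferroni correction. A
#' confirmatory k-means partition (seeded) reports the fraction of labels
#' that agree (maximized over label permutations).
#'
#' @param lifespans,values The two columns (e.g. lifespan and dissipation
#'   rate per clone).
#' @param k Number of clusters (default 3).
#' @param seed Seed for the confirmatory k-means initialization.
#' @return An object of class `"cluster_result"`: `k`, `labels`
#'   (ordered by increasing lifespan-centroid), `centroids` (standardized
#'   space), `pairwise_p` (Bonferroni-corrected, `k(k-1)/2` entries),
#'   `confirmatory_agreement`.
#' @export
cluster_lifespan_pairs <- function(lifespans, values, k = 3L, seed = 1L) {
  x <- cbind(lifespan = as.numeric(lifespans), value = as.numeric(values))
  if (!all(is.finite(x))) stop("non-finite values", call. = FALSE)
  n <- nrow(x)
  k <- as.integer(k)
  if (n < 3 * k)
    stop(sprintf("need >= 3k = %d points for k = %d clusters", 3 * k, k),
         call. = FALSE)
  z <- scale(x)
  if (any(!is.finite(z))) stop("degenerate column (zero variance)", call. = FALSE)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  # relabel clusters by increasing mean lifespan for reportable identity
  ord <- order(tapply(x[, 1], labels, mean))
  labels <- match(labels, ord)
  centroids <- t(vapply(seq_len(k), function(g) colMeans(z[labels == g, , drop = FALSE]),
                        numeric(2)))
  pairs <- utils::combn(k, 2)
  ncmp <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(x[labels == pr[1], 2],
                                        x[labels == pr[2], 2])$p.value)
  })
  pw <- pmin(1, pw * ncmp)   # Bonferroni
  names(pw) <- apply(pairs, 2, function(pr) sprintf("%d-%d", pr[1], pr[2]))
  km <- local({
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(seed)
    stats::kmeans(z, centers = k, nstart = 25)
  })
  agree <- max_label_agreement(labels, km$cluster, k)
  structure(list(k = k, labels = labels, centroids = centroids,
                 pairwise_p = pw, confirmatory_agreement = agree),
            class = "cluster_result")
}

max_label_agreement <- function(a, b, k) {
  perms <- permutations_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[b] == a))
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: k = %d, sizes %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  cat("  Bonferroni-corrected Wilcoxon p-values:\n")
  for (nm in names(x$pairwise_p))
    cat(sprintf("    clusters %s: p = %.3g\n", nm, x$pairwise_p[nm]))
  cat(sprintf("  confirmatory k-means agreement: %.1f%%\n",
              100 * x$confirmatory_agreement))
  invisible(x)
}

#' One-sample Wilcoxon test of the median Hurst exponent
#'
#' Tests whether the cohort median Hurst exponent differs from the
#' no-memory value 1/2 (or another null) with a two-sided one-sample
#' Wilcoxon signed-rank test.
#'
#' @param H_values Per-clone Hurst exponents (`n >= 6`).
#' @param H0 Null median (default 0.5).
#' @return A list with `median` and `p`.
#' @export
median_hurst_test <- function(H_values, H0 = 0.5) {
  H <- as.numeric(H_values)
  if (length(H) < 6) stop("need >= 6 Hurst values", call. = FALSE)
  if (all(H == H0)) stop("degenerate: all values equal the null median",
                         call. = FALSE)
  p <- suppressWarnings(stats::wilcox.test(H, mu = H0)$p.value)
  list(median = stats::median(H), p = p)
}

# Gumbel (maximum-extreme) distribution ---------------------------------

#' Gumbel (maximum) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Gumbel distribution of maximum extremes with `location` and
#' `scale` parameters, the limiting law of clone lifespans across a cohort.
#'
#' @param x,q,p Vector of quantiles / probabilities.
#' @param n Number of draws.
#' @param location,scale Parameters (months); `scale > 0`.
#' @param log Return the log-density.
#' @return `dgumbel` the density, `pgumbel` the CDF, `qgumbel` the
#'   quantiles, `rgumbel` random draws.
#' @name gumbel
NULL

#' @rdname gumbel
#' @export
dgumbel <- function(x, location = 0, scale = 1, log = FALSE) {
  z <- (x - location) / scale
  ld <- -z - exp(-z) - base::log(scale)
  if (log) ld else exp(ld)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, location = 0, scale = 1) {
  exp(-exp(-(q - location) / scale))
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, location = 0, scale = 1) {
  location - scale * base::log(-base::log(p))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, location = 0, scale = 1) {
  qgumbel(stats::runif(n), location, scale)
}

#' Maximum-likelihood Gumbel fit of clone lifespans
#'
#' Fits the Gumbel (maximum-extreme) distribution to a set of lifespans by
#' maximum likelihood (BFGS on the negative log-likelihood, moment-based
#' start `scale = sd * sqrt(6)/pi`, `location = mean - gamma * scale`),
#' then estimates the parametric-bootstrap bias of the mean-lifespan
#' estimator: replicates are drawn from the fitted law and the average
#' difference between the replicate sample mean and the fitted population
#' mean (`location + gamma * scale`) is reported. For a well-specified fit
#' the bias is zero within Monte-Carlo error — the sense in which the
#' empirical time-to-failure estimator is unbiased.
#'
#' @param L_values Lifespans in months (`n >= 8`).
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Seed for the bootstrap.
#' @return An object of class `"gumbel_fit"`: `location`, `scale`,
#'   `loglik`, `bias_estimate`, `n`.
#' @export
fit_gumbel_lifespans <- function(L_values, n_boot = 500L, seed = 1L) {
  L <- as.numeric(L_values)
  n <- length(L)
  if (n < 8) stop("need >= 8 lifespans", call. = FALSE)
  euler <- 0.5772156649015329
  s0 <- stats::sd(L) * sqrt(6) / pi
  m0 <- mean(L) - euler * s0
  nll <- function(par) {
    if (par[2] <= 0) return(Inf)
    -sum(dgumbel(L, par[1], par[2], log = TRUE))
  }
  opt <- stats::optim(c(m0, s0), nll, method = "BFGS")
  if (!is.finite(opt$value))
    stop("Gumbel likelihood optimization failed", call. = FALSE)
  loc <- opt$par[1]; sc <- opt$par[2]
  pop_mean <- loc + euler * sc
  bias <- local({
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(seed)
    mean(replicate(n_boot, mean(rgumbel(n, loc, sc)))) - pop_mean
  })
  structure(list(location = loc, scale = sc, loglik = -opt$value,
                 bias_estimate = bias, n = n, n_boot = as.integer(n_boot)),
            class = "gumbel_fit")
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("Gumbel lifespan fit: location = %.4g, scale = %.4g months (n = %d)\n",
              x$location, x$scale, x$n))
  cat(sprintf("  log-likelihood %.4g; bootstrap bias of mean-lifespan estimator %.4g months (%d reps)\n",
              x$loglik, x$bias_estimate, x$n_boot))
  invisible(x)
}

#' @export
coef.gumbel_fit <- function(object, ...) {
  c(location = object$location, scale = object$scale)
}

#' Power law of the time-to-failure in the proliferative capacity
#'
#' The lifespan of a clone scales as a power of its proliferative capacity.
#' Capacity is measured as the area under the total kinetic (trapezoidal
#' rule; alternatively the peak height), and `L = a * capacity^b` is fitted
#' with the same machinery as [fit_power_law()].
#'
#' @param batch A [kinetic_batch()], or a numeric vector of capacities.
#' @param L Lifespans; taken from the batch when omitted.
#' @param capacity `"auc"` (default) or `"peak"`.
#' @return A `power_law_fit` of `L` on capacity, with the capacities
#'   attached as attribute `"capacity"`.
#' @export
fit_ttf_power_law <- function(batch, L = NULL, capacity = c("auc", "peak")) {
  capacity <- match.arg(capacity)
  if (inherits(batch, "kinetic_batch")) {
    caps <- vapply(batch$clones, function(k) {
      if (capacity == "auc") {
        sum(diff(k$times) * (utils::head(k$total, -1) + utils::tail(k$total, -1)) / 2)
      } else max(k$total)
    }, 0)
    if (is.null(L)) L <- vapply(batch$clones, function(k) k$lifespan, 0)
  } else {
    caps <- as.numeric(batch)
    if (is.null(L)) stop("supply lifespans L with bare capacities", call. = FALSE)
  }
  fit <- fit_power_law(caps, L)
  attr(fit, "capacity") <- caps
  fit
}

#' Analytic dissipation rate of a clone from its reliability profile
#'
#' The deterministic core of a clonal reliability kinetic is modeled by the
#' `power_decay` family, `R(t) = (1 - t/L)^{k+1}`. The shape exponent is
#' estimated by regressing `log R(t_k)` on `log(1 - t_k/L)` through the
#' origin (the profile starts at `R = 1` exactly) over the pre-extinction
#' window, and the mean dissipation rate follows in closed form:
#' `beta_bar = k * log((L - lo)/(L - hi)) / (hi - lo)` with
#' `lo = dt`, `hi = L - 2 dt` — the analytic counterpart of fitting a
#' mean-reverting model to the failure-rate fluctuations, derived instead
#' from the shape of the reliability decline.
#'
#' @param prof A [reliability_profile()].
#' @param L Clone lifespan (months); defaults to the profile's last time.
#' @param dt_sample Sampling interval defining the window (default 2).
#' @return A list with `k` (shape exponent), `beta_bar` (1/month),
#'   `halflife` (months) and `n` (points used).
#' @export
analytic_dissipation <- function(prof, L = NULL, dt_sample = 2) {
  stopifnot(inherits(prof, "reliability_profile"))
  tt <- prof$times
  R <- prof$reliability
  if (is.null(L)) L <- max(tt)
  hi <- L - 2 * dt_sample
  use <- tt > 0 & tt <= hi & R > 0 & tt < L
  if (sum(use) < 3)
    stop("too few interior points for a family fit", call. = FALSE)
  x <- log(1 - tt[use] / L)
  y <- log(R[use])
  kp1 <- sum(x * y) / sum(x * x)
  k <- max(kp1 - 1, 1e-3)
  bb <- k * log((L - dt_sample) / (2 * dt_sample)) / (L - 3 * dt_sample)
  list(k = k, beta_bar = bb, halflife = log(2) / bb, n = sum(use))
}
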