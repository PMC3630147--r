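#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' list; all entries have the documented defaults and any subset can be
#' overridden.
#'
#' @param input Path to a kinetics table (for [run_analyze()]); `NULL`
#'   when an in-memory batch is passed instead.
#' @param outdir Output directory; `NULL` disables file output and the
#'   results are only returned.
#' @param trunc Length-2 truncation `(m, n)` of failure-rate series
#'   before memory/OU analysis (default `c(0, 2)`, the pre-extinction
#'   window).
#' @param rs_mode,mean_mode Rescaled-range options (see
#'   [rescaled_range()] and [failure_rate_memory()]).
#' @param ou_method OU estimator (see [estimate_ou()]).
#' @param ou_bias_correction Apply the median-unbiased small-sample
#'   correction in the per-clone OU fits (default `TRUE`; the clone
#'   windows are short).
#' @param drift_window Moving-average window for the drifting-mean fit.
#' @param regime_q,engraftment_months Regime-detection thresholds (see
#'   [detect_regimes()]).
#' @param cluster_k Number of cohort clusters.
#' @param seed Seed for every stochastic step.
#' @param verbose Print progress messages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, outdir = NULL, trunc = c(0L, 2L),
                            rs_mode = "overlap", mean_mode = "trend",
                            ou_method = "cls", ou_bias_correction = TRUE,
                            drift_window = 6L,
                            regime_q = 2, engraftment_months = 3,
                            cluster_k = 3L, seed = 1L, verbose = FALSE) {
  structure(list(input = input, outdir = outdir, trunc = as.integer(trunc),
                 rs_mode = rs_mode, mean_mode = mean_mode,
                 ou_method = ou_method,
                 ou_bias_correction = isTRUE(ou_bias_correction),
                 drift_window = as.integer(drift_window),
                 regime_q = regime_q, engraftment_months = engraftment_months,
                 cluster_k = as.integer(cluster_k), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

note <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
  invisible(NULL)
}

#' Analyze a clone end to end
#'
#' Runs the single-clone chain: reliability profile of the total kinetic
#' (and of each lineage plus the inferred HSC pool when lineages are
#' present), `(m, n)` truncation of the failure rate, Hurst analysis with
#' the clone's deterministic hazard trend as domain-specific mean, OU
#' estimation with half-life, drifting-mean fit of the moving-average
#' failure rate, and regime/extinction-transition detection.
#'
#' @param k A [clonal_kinetic()].
#' @param config A [pipeline_config()].
#' @return A list with elements `clone_id`, `profiles` (named list of
#'   `reliability_profile`s), `truncated`, `hurst`, `ou`, `drift`,
#'   `regimes`.
#' @export
analyze_clone <- function(k, config = pipeline_config()) {
  profiles <- list(clone = reliability_profile(k, "clone"))
  if (!is.null(k$lineages) && all(c("T", "B", "My") %in% names(k$lineages))) {
    lin <- lapply(c(T = "T", B = "B", My = "My"), function(s)
      tryCatch(reliability_profile(k, s), error = function(e) NULL))
    if (!any(vapply(lin, is.null, TRUE))) {
      profiles <- c(profiles, lin)
      profiles$HSC <- tryCatch(
        infer_hsc_reliability(profiles$clone, lin$T, lin$B, lin$My),
        error = function(e) NULL)
    }
  }
  prof <- profiles$clone
  tr <- truncate_failure_rate(prof, config$trunc[1], config$trunc[2])
  dissipation <- tryCatch(analytic_dissipation(prof, L = k$lifespan),
                          error = function(e) structure(list(error = conditionMessage(e)),
                                                        class = "analysis_skip"))
  # domain-specific mean: the clone's fitted deterministic hazard on the
  # truncated grid (discrete power_decay hazard at each left endpoint)
  trend <- NULL
  if (config$mean_mode == "trend" && !inherits(dissipation, "analysis_skip")) {
    kp1 <- dissipation$k + 1
    L <- k$lifespan
    dtv <- diff(prof$times)
    tl <- tr$times
    idx <- match(tl, prof$times[-length(prof$times)])
    trend <- (1 - ((L - tl - dtv[idx]) / (L - tl))^kp1) / dtv[idx]
  }
  hurst <- tryCatch(
    failure_rate_memory(tr$failure_rate, trend = trend,
                        rs_mode = config$rs_mode),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "analysis_skip"))
  # OU dissipation of the hazard fluctuations: fit on the relative
  # residuals around the deterministic hazard when a trend is available
  # (the hazard itself trends upward, so raw levels are not stationary),
  # else on the raw truncated series
  ou_series <- if (!is.null(trend) && all(trend > 0))
    tr$failure_rate / trend - 1 else tr$failure_rate
  ou <- tryCatch(estimate_ou(ou_series, tr$times,
                             method = config$ou_method,
                             bias_correction = config$ou_bias_correction),
                 error = function(e) structure(list(error = conditionMessage(e)),
                                               class = "analysis_skip"))
  ou_raw <- tryCatch(estimate_ou(tr$failure_rate, tr$times,
                                 method = config$ou_method),
                     error = function(e) structure(list(error = conditionMessage(e)),
                                                   class = "analysis_skip"))
  drift <- tryCatch({
    ma <- moving_average_mean(tr$failure_rate, config$drift_window)
    fit_mean_drift(ma, tr$times, k$lifespan, window = config$drift_window)
  }, error = function(e) structure(list(error = conditionMessage(e)),
                                   class = "analysis_skip"))
  regimes <- if (inherits(ou_raw, "ou_fit") && isTRUE(ou_raw$mean_reverting)) {
    tl <- prof$times[-length(prof$times)]
    tryCatch(detect_regimes(prof$failure_rate, tl, ou_raw,
                            q = config$regime_q,
                            engraftment_months = config$engraftment_months),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "analysis_skip"))
  } else structure(list(error = "no mean-reverting raw-scale OU fit"),
                   class = "analysis_skip")
  list(clone_id = k$clone_id, profiles = profiles, truncated = tr,
       hurst = hurst, ou = ou, ou_raw = ou_raw, dissipation = dissipation,
       drift = drift, regimes = regimes)
}

#' Run the full cohort analysis
#'
#' Applies [analyze_clone()] to every clone of a batch (failures are
#' quarantined per clone and listed, never silently dropped), then runs the
#' cohort statistics on the successful clones: power-law tendencies of the
#' OU dissipation rate and of its half-life versus lifespan, the median
#' Hurst test against 1/2, standardized clustering of (lifespan,
#' dissipation) pairs, the Gumbel lifespan fit, and the time-to-failure
#' power law in proliferative capacity. When `config$outdir` is set, per-
#' clone profile TSVs and a cohort JSON are written alongside a run log.
#'
#' @param batch A [kinetic_batch()], or a path to a kinetics table.
#' @param config A [pipeline_config()].
#' @return A list of class `"cohort_analysis"`: `clones` (per-clone
#'   results), `excluded` (named reasons), `cohort` (the cohort-level
#'   fits), `config`.
#' @export
run_analyze <- function(batch, config = pipeline_config()) {
  if (is.character(batch)) batch <- read_kinetics(batch)
  if (!inherits(batch, "kinetic_batch")) stop("not a kinetic_batch", call. = FALSE)
  if (length(batch) == 0) stop("empty input batch", call. = FALSE)
  results <- list(); excluded <- character(0)
  for (k in batch$clones) {
    res <- tryCatch(analyze_clone(k, config), error = function(e) e)
    if (inherits(res, "error")) {
      excluded[k$clone_id] <- conditionMessage(res)
      note(config, "clone %s excluded: %s", k$clone_id, conditionMessage(res))
    } else {
      results[[k$clone_id]] <- res
    }
  }
  if (length(results) == 0) stop("no clone could be analyzed", call. = FALSE)
  ok_ou <- vapply(results, function(r)
    inherits(r$ou, "ou_fit") && isTRUE(r$mean_reverting <- r$ou$mean_reverting), TRUE)
  L <- vapply(results, function(r) batch$clones[[r$clone_id]]$lifespan, 0)
  beta_ou <- vapply(results, function(r)
    if (inherits(r$ou, "ou_fit")) r$ou$beta else NA_real_, 0)
  beta_an <- vapply(results, function(r)
    if (!inherits(r$dissipation, "analysis_skip")) r$dissipation$beta_bar
    else NA_real_, 0)
  H_hat <- vapply(results, function(r)
    if (inherits(r$hurst, "hurst_fit")) r$hurst$hurst else NA_real_, 0)
  cohort <- list()
  # primary dissipation tendency: the analytic (family-shape) route
  use_an <- is.finite(beta_an) & beta_an > 0
  cohort$beta_vs_L <- tryCatch(fit_power_law(L[use_an], beta_an[use_an]),
                               error = function(e) NULL)
  cohort$halflife_vs_L <- tryCatch(
    fit_power_law(L[use_an], log(2) / beta_an[use_an]),
    error = function(e) NULL)
  # data route: per-clone OU dissipation of the failure-rate fluctuations
  use <- ok_ou & is.finite(beta_ou) & beta_ou > 0
  cohort$beta_vs_L_ou <- tryCatch(fit_power_law(L[use], beta_ou[use]),
                                  error = function(e) NULL)
  cohort$median_hurst <- tryCatch(median_hurst_test(H_hat[is.finite(H_hat)]),
                                  error = function(e) NULL)
  cohort$hurst_vs_L <- tryCatch(
    hurst_vs_lifespan_fit(L[is.finite(H_hat)], H_hat[is.finite(H_hat)]),
    error = function(e) NULL)
  cohort$clusters <- tryCatch(
    cluster_lifespan_pairs(L[use_an], beta_an[use_an], k = config$cluster_k,
                           seed = config$seed),
    error = function(e) NULL)
  cohort$gumbel <- tryCatch(
    fit_gumbel_lifespans(vapply(batch$clones, function(k) k$lifespan, 0),
                         seed = config$seed),
    error = function(e) NULL)
  cohort$ttf_power_law <- tryCatch(fit_ttf_power_law(batch),
                                   error = function(e) NULL)
  out <- structure(list(clones = results, excluded = excluded,
                        cohort = cohort, config = config),
                   class = "cohort_analysis")
  if (!is.null(config$outdir)) write_analysis(out, batch, config)
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d clones analyzed, %d excluded\n",
              length(x$clones), length(x$excluded)))
  if (!is.null(x$cohort$median_hurst))
    cat(sprintf("  median Hurst = %.3f (p = %.3g vs 0.5)\n",
                x$cohort$median_hurst$median, x$cohort$median_hurst$p))
  if (!is.null(x$cohort$beta_vs_L))
    cat(sprintf("  dissipation tendency: beta_bar = %.4g * L^%.3g\n",
                x$cohort$beta_vs_L$a, x$cohort$beta_vs_L$b))
  if (!is.null(x$cohort$gumbel))
    cat(sprintf("  Gumbel lifespans: location %.3g, scale %.3g months\n",
                x$cohort$gumbel$location, x$cohort$gumbel$scale))
  invisible(x)
}

write_analysis <- function(out, batch, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  for (r in out$clones) {
    for (nm in names(r$profiles)) {
      if (is.null(r$profiles[[nm]])) next
      write_results(r$profiles[[nm]],
                    file.path(config$outdir,
                              sprintf("%s_profile_%s.tsv", r$clone_id, nm)))
    }
  }
  summ <- cohort_summary(out, batch)
  jsonlite::write_json(summ, file.path(config$outdir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(sprintf("relkin %s", as.character(utils::packageVersion("relkin"))),
                 sprintf("seed %d; trunc (%d,%d); rs_mode %s; mean_mode %s; ou %s",
                         config$seed, config$trunc[1], config$trunc[2],
                         config$rs_mode, config$mean_mode, config$ou_method),
                 sprintf("clones analyzed: %d; excluded: %d",
                         length(out$clones), length(out$excluded)),
                 if (length(out$excluded) > 0)
                   sprintf("excluded %s: %s", names(out$excluded), out$excluded))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(NULL)
}

cohort_summary <- function(out, batch) {
  strip <- function(x, fields) {
    if (is.null(x)) return(NULL)
    y <- unclass(x)[fields]
    y[!vapply(y, is.null, TRUE)]
  }
  list(
    n_clones = length(out$clones),
    n_excluded = length(out$excluded),
    clones = lapply(out$clones, function(r) {
      list(clone_id = r$clone_id,
           lifespan = batch$clones[[r$clone_id]]$lifespan,
           hurst = if (inherits(r$hurst, "hurst_fit")) r$hurst$hurst else NULL,
           ou = strip(if (inherits(r$ou, "ou_fit")) r$ou else NULL,
                      c("mu", "sigma", "beta", "halflife", "n", "dt",
                        "normality_p", "mean_reverting")),
           dissipation = if (!inherits(r$dissipation, "analysis_skip"))
             r$dissipation else NULL,
           drift = strip(if (inherits(r$drift, "drift_fit")) r$drift else NULL,
                         c("c0", "c1", "t_c", "p", "window", "aic", "converged")),
           transition_time = if (inherits(r$regimes, "regime_labels"))
             r$regimes$transition_time else NULL)
    }),
    beta_vs_L = strip(out$cohort$beta_vs_L, c("a", "b", "aic", "n")),
    beta_vs_L_ou = strip(out$cohort$beta_vs_L_ou, c("a", "b", "aic", "n")),
    halflife_vs_L = strip(out$cohort$halflife_vs_L, c("a", "b", "aic", "n")),
    median_hurst = out$cohort$median_hurst,
    hurst_vs_L = strip(out$cohort$hurst_vs_L,
                       c("slope", "intercept", "p_slope", "aic")),
    clusters = strip(out$cohort$clusters,
                     c("k", "labels", "pairwise_p", "confirmatory_agreement")),
    gumbel = strip(out$cohort$gumbel,
                   c("location", "scale", "loglik", "bias_estimate", "n")),
    ttf_power_law = strip(out$cohort$ttf_power_law, c("a", "b", "aic", "n")))
}

#' Generate and write a synthetic cohort
#'
#' Wraps [gen_cohort()]: generates the batch, and when an output directory
#' is configured writes the kinetics TSV (the same dialect [read_kinetics()]
#' consumes) plus the ground-truth table. Deterministic under the spec
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param outdir Output directory or `NULL`.
#' @return The [gen_cohort()] result, invisibly when writing.
#' @export
run_simulate <- function(spec = cohort_spec(), outdir = NULL) {
  res <- gen_cohort(spec)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_results(res$batch, file.path(outdir, "kinetics.tsv"))
    write_results(res$truth, file.path(outdir, "ground_truth.tsv"))
    return(invisible(res))
  }
  res
}

#' Theory report for a ballistic family
#'
#' Materializes a family and reports its scalar theory quantities (initial
#' damage load, balance point, strict-increase onset, asymptotic constant,
#' mean dissipation over the automatic pre-extinction window, and the
#' dissipation half-life `log(2)/beta_bar`), optionally writing JSON and a
#' sampled curve TSV.
#'
#' @param spec A [density_family()].
#' @param outdir Output directory or `NULL`.
#' @param dt_sample Sampling step for the curve grid and the automatic
#'   integration bounds (default 2 months).
#' @return A list with the scalar report and the `theory_curves`.
#' @export
run_theory <- function(spec, outdir = NULL, dt_sample = 2) {
  cv <- make_family(spec)
  bb <- mean_dissipation(cv, dt_sample = dt_sample)
  report <- list(family = spec$family, L = spec$lifespan,
                 k = spec$exponent, lambda0 = cv$lambda0, t0 = cv$t0,
                 t_star = cv$t_star, c_L = cv$c_L,
                 beta_bar = as.numeric(bb),
                 beta_halflife = log(2) / as.numeric(bb),
                 bounds = as.numeric(attr(bb, "bounds")))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "theory.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tt <- seq(0, spec$lifespan * (1 - 1e-6), by = dt_sample)
    grid <- data.frame(time_months = tt, R = cv$R_fn(tt), f = cv$f_fn(tt),
                       lambda = cv$lambda_fn(tt), beta = cv$beta_fn(tt))
    write_results(grid, file.path(outdir, "theory_curves.tsv"))
  }
  list(report = report, curves = cv)
}
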