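Package: relkin
Title: Reliability and Failure-Rate Analysis of Clonal Repopulation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reliability-theory analysis of clonal hematopoietic stem cell
    (HSC) repopulation kinetics. Transforms percent-donor chimerism time
    series into discrete reliability, failure-probability, failure-density
    and failure-rate (hazard) profiles; infers the reliability of the
    unobserved HSC pool from lineage data through a common-cause structure
    balance; quantifies memory in failure-rate fluctuations with a
    rescaled-range (Hurst) analysis that admits a ballistic-trend
    domain-specific mean; fits mean-reverting Ornstein-Uhlenbeck models of
    the failure rate with drifting-mean extensions and phase-space regime
    detection of the extinction transition; provides a deterministic
    ballistic failure-rate theory (initial damage load, dissipation rate,
    imperfect-repair margin, lifespan asymptotics); and supplies
    cohort-level statistics (power-law tendencies of dissipation rate and
    half-life versus lifespan, standardized hierarchical clustering with
    Wilcoxon/Bonferroni comparisons, Gumbel lifespan fitting) together with
    seeded synthetic-data generators (ballistic clonal kinetics with lineage
    decomposition, structured cohorts, fractional Gaussian noise) so every
    stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
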