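# relkin

Reliability and failure-rate analysis of clonal hematopoietic stem cell
(HSC) repopulation kinetics.

A single HSC transplanted into an ablated host repopulates the blood for
a limited, clone-specific time — the lifespan, anywhere from 10 to
nearly 60 months — before the clone stops producing all mature lineages.
`relkin` is for researchers who have such clonal chimerism time series
(percent donor-type cells, total and per lineage, sampled every other
month) and want to treat the clone as a repairable system: to ask how
fast failures are generated, how fast repair dissipates them, and why
some clones live longer than others.

## The model in brief

For a kinetic sampled at times *t₁ … t_N* with values *y₁ … y_N*, the
realized repopulation work per interval is *w_j = |Δy_j|*, normalized by
the total *A = Σ w_j*. This gives discrete reliability statistics

- failure probability *F(t_k) = Σ_{j<k} w_j / A* (spent fraction of the
  work budget), reliability *R = 1 − F*,
- failure density *f_k = w_k / (A Δt_k)*,
- failure rate (hazard) *λ_k = f_k / R(t_k)*, which rises toward
  extinction.

The unobserved HSC pool's reliability is inferred from a common-cause
structure balance, `1 − (1−R_HSC)(1−R_clone) = 1 − (1−R_T)(1−R_B)(1−R_My)`.

Pre-extinction hazard fluctuations are modeled as a mean-reverting
Ornstein–Uhlenbeck process, *dλ = β(μ − λ)dt + σ dW*: the dissipation
rate *β* (half-life ln 2 ∕ β) quantifies repair. Their memory is measured
by a rescaled-range (Hurst) analysis adapted to short, trended series
(overlapping windows, Anis–Lloyd small-sample correction, the clone's
deterministic hazard as a domain-specific mean); mean reversion reads as
anti-persistence, *H < ½*. A deterministic ballistic theory supplies the
noise-free counterpart — closed-form *λ(t)*, dissipation *β(t) = −f′/f*,
initial damage load *λ(0)* (larger for shorter-lived clones), the
imperfect-repair margin *λ − β > 0*, and the universal terminal
divergence *λ(t) ~ c_L/(L − t)*. The terminal break-down of mean
reversion (extinction transition) is detected as a sustained excursion of
the hazard above *μ + 2σ_stat*, driven by a slowly diverging mean
*μ(t) = c₀ + c₁/(t_c − t)* with critical limit *t_c* just below the
lifespan. Cohort statistics relate dissipation and its half-life to
lifespan by power-law tendencies, cluster (lifespan, dissipation) pairs,
and fit the Gumbel law of lifespans.

Seeded generators (`gen_clone`, `gen_hazard_clone`, `gen_cohort`,
`gen_fgn`) emulate the study design — 38 clones, 2-month sampling,
lineage decomposition, an imposed dissipation–lifespan power law — so
the entire chain is testable without experimental data.

## Worked example

```r
library(relkin)

# the discrete reliability decomposition of a toy kinetic
k <- clonal_kinetic("toy", times = c(0, 2, 4, 6, 8),
                    total = c(0, 10, 20, 10, 0))
p <- reliability_profile(k)
p$failure_prob   # 0.00 0.25 0.50 0.75 1.00
p$failure_rate   # 0.1250 0.1667 0.2500 0.5000  -- rises toward extinction

# a synthetic study-sized cohort, analyzed end to end
co  <- gen_cohort(cohort_spec(seed = 1))
ana <- run_analyze(co$batch)
ana
#> Cohort analysis: 38 clones analyzed, 0 excluded
#>   median Hurst = 0.310 (p = 3.76e-05 vs 0.5)
#>   dissipation tendency: beta_bar = 0.004353 * L^1.04
#>   Gumbel lifespans: location 28.6, scale 12.7 months

# one long-lived clone in detail
r <- ana$clones[["clone18"]]      # lifespan 59.6 months
r$hurst
#> Hurst exponent: H = 0.2024 (R^2 = 0.891; ...)
#>   memory class: anti-persistent
r$ou
#> Ornstein-Uhlenbeck fit (cls), n = 27, dt = 2 months
#>   mu = -0.0161932  beta = 0.353493 /month  sigma = 0.0537134
#>   dissipation half-life = 1.961 months; residual normality p = 0.0912
r$dissipation$beta_bar            # analytic route: 0.328 (truth 0.298)
r$drift
#> Drifting-mean fit: mu(t) = 0.077206 + 2.72897/(59.5953 - t)^1
#>   critical limit t_c = 59.6 months; AIC = -218.9; MA window = 6
```

Reading the numbers: the clone's hazard fluctuations are strongly
anti-persistent (H = 0.20 « 0.5) — every surge in the failure rate is
answered by a decrease, the fingerprint of active repair. Both
dissipation estimates (0.33 analytic, 0.35 from the OU fit; generator
truth 0.30) say perturbations are damped with a half-life of about 2
months. Across the cohort the fitted tendency `beta_bar ≈ 0.0044 · L^1.04`
recovers the imposed law `0.005 · L`: longer-lived clones dissipate
failures faster. The drifting-mean fit places the critical limit of the
mean failure rate at the clone's lifespan — mean reversion around a
slowly diverging mean, ending in the extinction transition.

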