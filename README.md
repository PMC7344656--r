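# careaccess

Small-area primary care access and cardiometabolic risk modelling.

`careaccess` is for epidemiologists and health-services researchers asking a
recurring small-area question: **does geographic access to primary care
explain the between-area variation in cardiometabolic risk factors (CMRFs)?**
It implements the full analysis chain for a region of small census areas
(persons nested in areas):

1. **2SFCA access index.** The two-step floating catchment area method on
   planar point tables. Step 1 gives each provider site *j* a
   provider-to-population ratio over the areas within the radial buffer
   *d₀*:

   *Rⱼ = Sⱼ / Σᵢ pᵢ*,  (sum over areas *i* with centroid within *d₀* of *j*)

   where *Sⱼ* is the site's GP count and *pᵢ* the area's adult population.
   Step 2 sums reachable sites per area: *Aᵢ = Σⱼ Rⱼ*, practitioners per
   capita. A coverage sensitivity report counts area centroids within
   candidate radii (default 1, 16, 30 km).

2. **Cohort construction.** Guideline cut-points dichotomise seven CMRF
   tests (fasting blood sugar ≥ 7.0 mmol/L, HbA1c > 7.5%, total cholesterol
   ≥ 5.5 mmol/L, HDL < 1 mmol/L, albumin–creatinine ratio ≥ 30,
   eGFR < 60 mL/min/1.73 m², BMI ≥ 30 kg/m²), the most recent in-window test
   per person and factor is kept, and incomplete records are excluded with a
   per-reason log.

3. **Nested multilevel models.** Five nested two-level random-intercept
   logistic regressions per risk factor (null; +access; +sex+age;
   +disadvantage; +access), fitted by maximum likelihood with adaptive
   Gauss–Hermite quadrature written for this package. Continuous covariates
   (area disadvantage score, access index) enter mean-centred per area-level
   SD, so their odds ratios are per-SD.

4. **Contextual-effect statistics.** Latent-variable intraclass correlation
   ICC = τ²/(τ² + π²/3), median odds ratio
   MOR = exp(√(2τ²)·Φ⁻¹(0.75)), proportional change in variance (PCV)
   against the null model, the variance uniquely explained by access
   (M4 → M5), AIC, and likelihood-ratio tests along the nesting arrows.

A seeded synthetic-region generator (areas, provider sites, persons, binary
outcomes from the generative analogue of the fully adjusted model) makes the
whole pipeline testable without restricted health data.

## Worked example

Simulate a 120-area region, compute access, build the low-HDL cohort and fit
the model ladder:

```r
library(careaccess)

cfg <- region_config(n_areas = 120, pop_range = c(200, 800),
                     n_provider_sites = 20, gp_total = 75,
                     irsd_missing = 0, seed = 2024)
areas     <- generate_areas(cfg)
providers <- generate_providers(cfg, areas)
areas     <- compute_access(areas, providers, buffer_km = 30)
coverage_sensitivity(areas, providers, c(1, 16, 30))
#>   buffer_km n_covered n_total fraction
#> 1         1         4     120   0.0333
#> 2        16       110     120   0.917
#> 3        30       120     120   1

persons <- generate_persons(areas, sampling_fraction = 0.5,
                            cmrfs = "HDL", seed = 2025)
persons <- simulate_outcomes(persons, areas,
                             default_outcome_params("HDL"), seed = 2026)
records <- select_most_recent(persons, c("2012-01-01", "2017-12-31"))
records <- exclude_incomplete(records, areas)

lad <- run_ladder(records, areas)
lad
#> Nested risk-model ladder for HDL
#>   model    aic  loglik   tau2 icc_pct   mor pcv_pct
#> 1 M1    22589. -11293. 0.0670   2.00   1.28   NA
#> 2 M2    22585. -11290. 0.0614   1.83   1.27   -8.43
#> 3 M3    21258. -10620. 0.0708   2.11   1.29    5.62
#> 4 M4    21217. -10599. 0.0363   1.09   1.20  -45.9
#> 5 M5    21213. -10595. 0.0316   0.952  1.18  -52.8
#> Proportional variance explained by access (M4 -> M5): -12.78%
```

Read the ladder top to bottom: the null model puts ~2% of outcome variance
between areas (ICC 2.0%, MOR 1.28 — the median odds penalty of moving an
identical person to a higher-risk area). Sex and age alone do not shrink the
area variance (M3), area disadvantage absorbs about half of it (M4), and
adding access explains a further ~13% of what remained. The fully adjusted
access odds ratio is per SD of the area-level access distribution:

```r
odds_ratios(lad$fits$M5)
#>  term            or or_low or_high   p_value
#>  ...
#>  irsd_z      0.834  0.794   0.875  2.05e-13
#>  access_z    0.938  0.893   0.984  9.48e-3
```

so here one SD more access lowers the odds of low HDL by ~6% — the simulated
region was generated with exactly this kind of weak protective effect.
`tidy()`, `glance()` and `autoplot()` methods are available for fits and
ladders, and `run_study()` drives the whole pipeline (simulate-or-load →
access → cohort → ladders → CSV/GeoJSON/JSON outputs plus a manifest that
reproduces the run bit-for-bit).

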