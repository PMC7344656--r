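---
title: "Methods: small-area access to primary care and cardiometabolic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area access to primary care and cardiometabolic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careaccess)
```

# The question and the data model

`careaccess` studies whether geographic access to primary care explains
between-area variation in binary cardiometabolic risk outcomes. Its data
model has three point tables on a common projected planar frame measured in
kilometres:

* **areas** — small census areas with a centroid, an adult population count
  `adult_pop`, and a socioeconomic disadvantage score `irsd` (higher = less
  disadvantaged);
* **providers** — primary care service locations with a general practitioner
  head count `gp_count`;
* **persons** — test records (person, area, sex, age band, risk-factor tag,
  value, date).

All user-facing functions take and return data frames, so the pipeline
chains with the pipe.

# The 2SFCA access index

The two-step floating catchment area method balances supply and demand
inside a radial buffer of distance $d_0$. Step 1 assigns each provider site
$j$ the ratio $R_j = S_j / \sum_i p_i$ over areas whose centroids lie within
$d_0$ of the site; step 2 gives each area $i$ the access index
$A_i = \sum_j R_j$ over sites within $d_0$ of its centroid, in practitioners
per capita (`access_per_1000` rescales for reporting only).

Numerical and semantic choices:

* **Distance** is straight-line Euclidean on the planar frame. No geodesy,
  no road network, no travel time: the index measures radial reachability
  only.
* **Boundary inclusive** ($d \le d_0$). "Within a buffer" is ambiguous at
  the boundary; inclusivity is fixed once so results are reproducible. The
  choice only matters for points exactly on the circle.
* **Degenerate catchments.** A site whose catchment is empty or has zero
  total population has an undefined ratio; it is excluded from step 2 with a
  warning rather than silently contributing $R_j = 0$, because an undefined
  ratio usually signals a data problem (mis-geocoded site, empty frame).
  Areas reaching no usable site get $A_i = 0$.
* **Both steps must share one buffer**; `access_index()` refuses a buffer
  different from the one `provider_ratios()` used.

The method conserves supply: $\sum_i p_i A_i$ equals the total GP count over
sites with usable catchments, an algebraic identity of the two steps that
the test suite checks to $10^{-10}$ on random regions. The default buffer is
30 km with a 1/16/30 km sensitivity report, the configuration appropriate to
a mixed urban–rural coastal region where 1 km covers only about half the
area centroids.

# Cohort construction

Seven risk factors are dichotomised at guideline cut-points with the printed
boundary semantics (`risk_thresholds()`): values exactly at a `>=` threshold
are higher risk (FBSL 7.0, TC 5.5, ACR 30, BMI 30), values exactly at a
strict `>` or `<` threshold are not (HbA1c 7.5, HDL 1.0, eGFR 60).

`select_most_recent()` keeps, per person and risk factor, the latest test
inside the study window (default 2012-01-01 to 2017-12-31). Ties on the date
are broken by the highest record identifier — an arbitrary but deterministic
and auditable rule. `exclude_incomplete()` performs listwise exclusion
(missing sex, age band, outcome, area link, or area disadvantage score) with
a per-reason count log; missing area IRSD is expected to dominate in
practice, which is why it is a first-class exclusion reason rather than an
imputation target.

# The nested model ladder

For each risk factor five nested two-level logistic models are fitted, all
with a random intercept $u_j \sim N(0, \tau^2)$ for areas:

| model | fixed effects |
|---|---|
| M1 | intercept |
| M2 | + access (per SD) |
| M3 | intercept + sex + age band |
| M4 | M3 + disadvantage (per SD) |
| M5 | M4 + access (per SD) |

Reference categories are female and ages 18–29. The continuous covariates
are standardised $(x - \bar x)/s$ with **area-level, unweighted** constants
computed once per analysis dataset and shared by all five models (and by the
outcome simulator). Person-level constants would weight populous areas more
heavily; the area-level choice matches the interpretation of "per SD of the
area distribution" and is recorded in the run manifest and fit objects.
Rows are persons (one most-recent test per person and factor), not test
events.

## Estimation

The marginal likelihood integrates the random intercept out of each area's
Bernoulli likelihood. Each one-dimensional integral is approximated by
**adaptive Gauss–Hermite quadrature**: nodes are recentred at the
conditional mode of the area's random effect and rescaled by the conditional
curvature, so accuracy holds even for large cluster sizes where naive
Gauss–Hermite fails. Fifteen nodes are the default; the test suite checks
agreement with dense-grid (trapezoid, 20,001-point) integration to $10^{-6}$
and that the $\sigma = 0$ case reduces exactly to the ordinary logistic
log-likelihood.

Implementation details that matter:

* Conditional modes are found by damped Newton iterations on the strictly
  concave per-area objective (step-halving guarantees ascent; steps are
  clamped to ±20 to survive saturated starts), vectorised across areas, and
  warm-started between likelihood evaluations within one fit.
* The optimiser is L-BFGS-B over $(\beta, \log\sigma)$ with analytic scores
  obtained from the Fisher identity (posterior node weights at the same
  quadrature nodes), started from the ordinary logistic fit and
  $\log\sigma = \log 0.3$. $\log\sigma$ is boxed to $[-7, 2.5]$: below the
  box the fit is statistically indistinguishable from $\tau^2 = 0$, above it
  the latent scale is far outside the plausible logistic range. A stalled
  quasi-Newton line search (stale curvature with a large score) triggers up
  to three restarts from the stalled point.
* Convergence requires the optimiser's own criterion plus a score sup-norm
  below $10^{-5}\max(1, |\ell|)$; fits reaching the lower box are reported
  as `tau2 = 0` with `boundary = TRUE`, their fixed effects equal to the
  ordinary logistic MLE.
* Standard errors come from the inverse of a central finite-difference
  Hessian of the marginal log-likelihood at the optimum; they can be skipped
  (`se = FALSE`) in simulation studies that only need point estimates.
* AIC is $-2\ell + 2(p + 1)$, counting the variance parameter.

Separation or single-class outcomes raise errors; non-converged fits are
returned flagged, and `run_ladder()` records per-model failures instead of
aborting the ladder.

## Contextual-effect statistics

From each fitted variance: latent-variable
$\mathrm{ICC} = \tau^2/(\tau^2 + \pi^2/3)$ (the logistic threshold model
puts $\pi^2/3$ of variance at the person level); median odds ratio
$\mathrm{MOR} = \exp\!\big(\sqrt{2\tau^2}\,\Phi^{-1}(0.75)\big)$; and the
proportional change in variance
$\mathrm{PCV} = 100(\tau^2_m - \tau^2_{\mathrm{ref}})/\tau^2_{\mathrm{ref}}$
against the null model (negative = explained, positive = inflated — sex and
age can legitimately inflate the area variance). The variance uniquely
attributable to access is the PCV from M4 to M5. The MOR closed form is the
standard one; the package validates it by round-tripping published
(τ², MOR) pairs, which agree to the last printed digit — the resolution that
rounded published variances support. Likelihood-ratio tests follow the
nesting arrows actually available (M1→M2, M1→M3, M3→M4, M4→M5; M2 is not
nested in M3), asserted before each test.

# The synthetic-region generator

The generator is first-class, tested code; it defines the study conditions
under which the statistical guarantees are verified.

* **Frame.** Default 980 areas of 200–800 adults, uniform centroids over a
  40 × 140 km frame (~5600 km², an elongated coastal strip), 165 provider
  sites with 611 GPs placed near population-weighted area centroids (supply
  tracks density), disadvantage scores $N(976.7, 98.6^2)$ with 2% missing
  completely at random.
* **Persons.** A configurable fraction of each area's adults (default 0.25)
  is tested per risk factor; sex is Bernoulli(0.48 male), ages follow a
  mildly older-skewed 7-band mix, test dates are uniform in the window, and
  10% of person–factor pairs carry one extra earlier record so
  most-recent-test selection has real work. The cohort's sex/age mix is not
  derivable from published margins, so these are explicit defaults, not
  inferences.
* **Outcomes.** The generative model is the analogue of M5: one
  $u_j \sim N(0, \tau^2)$ per area (per risk factor), linear predictor from
  sex, age band, and the standardised area covariates, Bernoulli outcomes.
  `default_outcome_params()` provides per-factor parameter sets with
  prevalences 4–34%, covariate effects of the magnitude seen in fully
  adjusted models of this kind, and residual variances 0.013–0.062; the
  intercept is calibrated numerically (sex/age enumerated, Gaussian terms
  integrated by quadrature) so the marginal prevalence hits its target.

What the generator does **not** emulate: realistic coastline or road
geometry, travel times, spatially autocorrelated disadvantage, provider
opening hours or bulk-billing, repeat-test value trajectories (values are
either simulated as final binary outcomes or supplied), ethnicity or blood
pressure. Passing tests therefore demonstrate the estimators' statistical
correctness under the stated generative model — not that any real region
satisfies that model.

# Study conditions for the statistical guarantees

Chosen once, at sizes that keep the full suite within a routine test run:

* **Parameter recovery**: 300 areas × 100 persons, $\tau^2 = 0.1$, access
  effect −0.09 and disadvantage effect −0.21 per SD, 20 replicate fits of
  M5; means of $\hat\tau^2$, $\hat\beta_{\mathrm{access}}$ and
  $\hat\beta_{\mathrm{irsd}}$ must sit within 3 Monte-Carlo SEs of truth and
  the replicate access ORs must bracket $e^{-0.09}$.
* **Type-I error**: 120 areas × 40 persons, access-null generative model,
  200 replicates of the M4→M5 likelihood-ratio test at order-7 quadrature;
  the rejection rate must lie within 3 binomial SEs of 5%.
* **Generator variance check**: 300 areas × 200 persons, 20 replicates; the
  between-area variance of empirical logit-prevalences, corrected for
  binomial inflation, must match the generative $\tau^2$.

# Known limitations

* Radial buffers ignore road networks, affordability and acceptability of
  services; the access index is reachability only.
* The binary 30 km catchment has no distance decay (no kernel-weighted or
  enhanced 2SFCA variants).
* Models are two-level with random intercepts only — no random slopes, no
  third level, no spatial correlation between neighbouring areas beyond
  what the shared intercept captures.
* Wald intervals and AIC are asymptotic; boundary fits ($\tau^2 = 0$) make
  the usual likelihood-ratio chi-square for the variance conservative.
* Cross-sectional by construction: nothing here supports causal claims
  about access and risk.
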