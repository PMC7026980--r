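---
title: "Methods: grouped stratified Cox models for long-term PM2.5 mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grouped stratified Cox models for long-term PM2.5 mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pmcohort implements the analysis machinery of national-scale cohort
studies of long-term fine-particle exposure and cause-specific mortality:
an open cohort of beneficiaries aged 65+ is followed month by month, each
person-month carries a trailing 12-month mean PM2.5 exposure at the
then-current residence, and cause-specific death hazards are modeled by
Cox proportional hazards with very fine baseline stratification. This
vignette explains the model, the numerical choices, and what the synthetic
study worlds do and do not establish.

## The model

For beneficiary $i$ at follow-up month $t$ in stratum $s$ (one-year age
bin x sex x race x ZIP code, optionally x SES tertile), the cause-$c$
hazard is

$$\lambda_{c}(t \mid s, x) = \lambda_{0,c,s}(t)\, e^{\beta_c' x_{it}},$$

where $x_{it}$ contains the exposure terms: the 12-month mean PM2.5 (in
ug/m3, so risk ratios per 10 ug/m3 are $e^{10\beta}$), or a restricted
cubic spline basis of it, or its residual after regressing out NO2, plus
optional interaction and adjustment terms. Deaths from causes outside $c$
censor that month (cause-specific hazard convention). Results are
reported as RR per 10 ug/m3 with Wald 95% intervals.

**Time axis.** Analysis time is months since cohort entry (entry = the
later of the study start and eligibility). With ZIP code and age inside
the strata, a calendar-time axis would make every risk set share a single
ZIP-month exposure value and destroy identifiability; on the follow-up
axis, members of a risk set entered in different calendar months and so
carry different exposures. All identification of the exposure slope is
therefore *within ZIP over calendar time* — exactly what the fine
stratification is designed to enforce.

**Ties.** Monthly resolution makes ties massive, and the Breslow
approximation is the only tie rule whose partial likelihood depends on
the data only through per-risk-set sufficient statistics. With event
counts $d_{st}$ and cell weights $w$ (number of person-months sharing a
stratum, time and covariate vector),

$$\ell(\beta) = \sum_{s,t}\Big[\sum_{\text{events}} \beta'x \;-\;
  d_{st}\,\log \sum_{\text{at risk}} w\, e^{\beta'x}\Big].$$

This is why the grouped-cell compression is *exact*, not an
approximation: the package asserts equality of the log-likelihood,
gradient, information, coefficients and standard errors between grouped
and raw evaluation to 1e-8 in its tests. Cell keys match covariates
exactly (no rounding) by default; exposures are shared ZIP-month values,
which is where the compression comes from.

**Optimization.** Newton–Raphson with analytic gradient and observed
information, step-halving (up to 10 halvings), convergence when the
relative log-likelihood change falls below 1e-8, at most 50 iterations.
Exponentials are guarded by subtracting the per-risk-set maximum of the
linear predictor. Risk sets without events contribute nothing and are
dropped before any floating-point work. A monotone likelihood (e.g. a
perfectly separating covariate) is detected by coefficient divergence or
degenerating information and flagged; downstream risk-ratio and curve
functions refuse unconverged fits. All sums run in a canonical sorted
cell order, so results are bit-identical across data.table thread
settings.

## Exposure handling

The trailing window is months $t-11 \ldots t$ *including* the current
month, for every at-risk month — a time-varying covariate must exist at
every month, not only the death month, and a rolling 12-month mean is the
natural reading. Windows crossing a residential move average each month's
then-current ZIP; months before the first recorded residence segment use
that segment's ZIP. Person-months whose window is incomplete leave the
risk set and are counted (never imputed). Grid-to-ZIP matching is
great-circle nearest with ties broken to the smaller grid identifier;
the warm season for ozone is April–September, the standard U.S.
convention; both are configurable.

**Two-stage non-traffic PM2.5.** Stage one is ordinary least squares of
12-month PM2.5 on 12-month NO2, pooled over all ZIP-months; the residual
is the exposure in stage two. Pooling (rather than one regression per
ZIP) keeps the residual on a single interpretable concentration scale; a
per-ZIP variant exists behind a switch. The residual is exactly
orthogonal to NO2 by construction; its validity as a "non-traffic"
measure is probed by correlating annual residuals against an EC-like
traffic tracer and a sulfate-like secondary tracer.

## Restricted cubic splines

The basis is the restricted truncated-power form: $b_1(x) = x$ and, for
interior knots $k_j$,

$$b_{j+1}(x) = \big[(x-k_j)_+^3 - (x-k_{m-1})_+^3\tfrac{k_m-k_j}{k_m-k_{m-1}}
 + (x-k_m)_+^3\tfrac{k_{m-1}-k_j}{k_m-k_{m-1}}\big] / (k_m-k_1)^2 .$$

Division by the squared knot span keeps all columns in exposure units.
Several equivalent parameterizations exist; the package asserts
equivalence at the *curve* level (refitting with translated knots
reproduces the curve to 1e-6), not the coefficient level. Knots default
to quantiles of the person-month exposure distribution — (10, 50, 90)%
for three knots, (5, 35, 65, 95)% for four, (5, 27.5, 50, 72.5, 95)% for
five — because the partial likelihood weights person-months, not
beneficiaries. Curves are referenced to 0 ug/m3; the restriction makes
the basis linear below the first knot, so evaluation down to zero is a
well-defined, documented linear extrapolation. Knot counts are compared
by AIC on the partial likelihood ($2k - 2\ell$), ties to fewer knots;
"performance" is not otherwise defined for a partial likelihood, and AIC
is the standard choice.

Effect modification uses a single joint fit with exposure-by-level
interactions; level RRs are $e^{10(\beta + \gamma_\ell)}$ with
delta-method intervals from the joint covariance. 95% intervals are
reported without multiplicity correction, mirroring how such analyses
are conventionally presented. Levels without events — or whose risk sets
carry no exposure contrast, which leaves their interaction aliased — are
flagged and omitted.

## The synthetic study worlds

The generator emulates the structure, not the geography, of a national
Medicare-like study over 2000–2008 (108 months):

* 500 ZIP codes, 74% of beneficiaries urban; per-ZIP PM2.5 split into a
  non-traffic and a traffic component with urban means above non-urban;
  overall 12-month mean ~10.3 ug/m3, sd ~3.1.
* A seasonal cycle (amplitude 1.5 ug/m3) that cancels exactly in
  12-month means, a linear secular decline of 2.8 ug/m3 across the
  window, and AR(1) month-to-month noise (phi = 0.4, marginal sd 1.5
  non-traffic / 0.6 traffic) — the within-ZIP temporal variation that
  identifies the slope under ZIP strata.
* NO2 = base + 1.5 ppb per ug/m3 of traffic PM plus spatial noise whose
  variance is solved in closed form so the analytic 12-month PM2.5–NO2
  correlation equals 0.59; an unattainable target errors out rather than
  silently under-delivering. Warm-season ozone correlates with PM2.5 at
  ~0.24 through the secondary component.
* Annual EC-like (proportional to the traffic share) and sulfate-like
  (secondary share) tracers; ZIP income by year with the 2000 and 2003
  source years absent, exercising the carry-forward rule.
* An open cohort: 75% prevalent at study start (entry ages 65+ from a
  truncated exponential), later entrants mostly at exactly 65; 55%
  female; race mix dominated by White (85%); residential moves at
  0.25%/month. Monthly death draws use a Gompertz-like baseline
  (0.0015/month at 65, log-slope 0.075/year, male x1.5) times the
  planted exposure effect; the cause mix follows the national elderly
  cause-of-death distribution (CVD 40%, cancer 23%, respiratory 11%, ...)
  and ICD-10 roots are drawn uniformly within each cause's ranges.
* Planted risk ratios per 10 ug/m3 sit at cause-family level — CVD
  1.088, respiratory 1.056, cancer 1.025, accidental ~1, other
  non-accidental 1.051 — so any modeled cause that aggregates a single
  family has an exactly proportional hazard with a well-defined truth.
  An all-cause truth exists only under a uniform planted RR, which the
  generator supports as an override. Ground truth travels in a sidecar
  file; recovery tests read it from nowhere else.

Discrete-time Bernoulli hazards match the monthly analysis resolution;
at monthly death probabilities far below one they agree with the
continuous-time hazard to first order, and the recovery experiments
quantify the residual gap (none detectable at the tested scales).

**What passing tests show — and do not.** The worlds establish that the
machinery is correct: exact grouping, oracle-equivalent fits, nominal
coverage, orthogonal residuals, recoverable planted contrasts. They do
not emulate real exposure-measurement error, confounding by unmeasured
personal characteristics, cause-of-death miscoding, or true geography,
so passing them says nothing about those threats to validity in real
data.

## Problem sizes and experiment design

The calibration experiments report at these sizes, chosen to give stable
Monte-Carlo summaries: parameter recovery at 50,000 beneficiaries x 108
months x 100 seed replicates (two family-aligned causes per replicate);
spline type-I error at 2,000 x 36 x 100; slope-change recovery at
20,000 x 84 x 20; attenuation at 30,000 x 84, three replicates per
traffic-effect setting. The attenuation and slope-change worlds raise
the traffic AR(1) sd (1.5) and, for the slope change, the non-traffic
temporal variance, because those contrasts are identified purely within
ZIP over time and the default temporal variance leaves them underpowered
at desk scale; this is a property of the design (ZIP strata absorb all
spatial contrast), not of the estimator.

## Known limitations

* Breslow ties only; no Efron or exact corrections (they would break
  exact grouping), no frailty, no robust variance, no time-varying
  coefficients.
* The cause map is range-based on three-character ICD-10 roots; the
  cancer block is bounded at D48 (neoplasms chapter), a deliberate
  reading of a "C–D" range that would otherwise swallow non-neoplasm
  codes.
* The first-stage NO2 regression interprets the residual as non-traffic
  PM2.5 only as well as NO2 proxies traffic; the attenuation experiment
  shows second-stage estimates carry some contamination when the NO2
  noise is large.
* Ozone-adjusted models consume a per-ZIP warm-season mean and, when
  monitor locations are supplied in the run configuration, restrict to
  ZIP codes within the configured radius (default 6 miles) of a monitor;
  without a monitor list all ZIP codes are used.
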