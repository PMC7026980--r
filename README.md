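# pmcohort

Cause-specific survival analysis of long-term fine-particle (PM2.5)
exposure in very large open cohorts of elderly beneficiaries — the
workhorse design of national air-pollution mortality studies, packaged
with a synthetic Medicare-like cohort generator so every stage is
testable without restricted data.

The core computation is a stratified Cox proportional hazards model on
person-months. For beneficiary months in stratum *s* (one-year age bin x
sex x race x ZIP code, optionally x SES tertile) the cause-*c* hazard is

    lambda_c(t | s, x) = lambda_0cs(t) * exp(beta_c' x)

with *x* the trailing 12-month mean PM2.5 at the then-current residence
(or its restricted-cubic-spline basis, or its NO2 residual), and deaths
from other causes censoring (cause-specific hazards). With Breslow tie
handling, the partial likelihood depends on the data only through
grouped sufficient statistics — cells keyed by (stratum, follow-up
month, covariate vector) with at-risk and event counts — so billions of
person-months compress losslessly before fitting. Newton–Raphson with
analytic gradient and observed information produces coefficients,
model-based covariance and risk ratios per 10 ug/m3.

Around the engine:

* **Cohort model** — ICD-10 cause-of-death grouping over editable code
  ranges (IHD I20–I25 inside CVD I00–I99 inside non-accidental A–R, ...),
  one-year age bins with a pooled 90+ bin, ZIP-income SES tertiles by
  year with the missing-year carry rule.
* **Exposure** — nearest-grid matching, 12-month moving averages across
  residential moves, warm-season (Apr–Sep) ozone, low-exposure ZIP
  restriction (below 8/10/12 ug/m3), monitor-radius subsets, and the
  two-stage "non-traffic PM2.5": regress 12-month PM2.5 on NO2, use the
  residual as the exposure.
* **Exposure–response** — restricted cubic splines (3–5 knots) with RR
  curves against a 0 ug/m3 reference and delta-method bands; AIC-based
  knot comparison; effect modification through exposure-by-subgroup
  interactions in a single joint fit.
* **Synthetic data** — ZIP-level correlated PM2.5/NO2/ozone surfaces
  (urban > non-urban, 12-month PM2.5–NO2 correlation calibrated to 0.59
  in closed form), tracer species, and cause-specific deaths from known
  planted risk ratios, emitted with a ground-truth sidecar.
* **Pipeline** — a config-driven `run_analysis()` covering the
  causes x (base/SES/ozone) x (total/non-traffic) x (linear/spline)
  matrix, plus `inst/cli/pmcohort.R` with `simulate`/`validate`/`run`
  subcommands.

## Worked example

```r
library(pmcohort)

cfg <- sim_config(n_beneficiaries = 20000, n_zips = 50, n_months = 108,
                  base_hazard_65 = 0.003)
st  <- simulate_study(cfg, seed = 42)

expo <- person_exposure_12mo(st$cohort, st$residence, st$exposures$pm25)
pm   <- expand_person_months(st$cohort, st$residence, expo,
                             cause = "All CVD", ses = st$ses)
fit  <- pm_cox(pm, ses_mode = "stratum")
rr_per_10(fit)
```

```
#>        rr      lo95      hi95
#> 1.4525346 0.7644004 2.7601461
```

The planted all-CVD risk ratio in this world is 1.088 per 10 ug/m3
(`st$truth$family_rr_per10$CVD`); the fitted RR of 1.45 with interval
(0.76, 2.76) covers it — at 20k beneficiaries the interval is wide
because, with ZIP codes inside the strata, only within-ZIP temporal
exposure contrast identifies the slope (the packaged coverage experiment
runs 100 such worlds at 50k to show the intervals are calibrated). A
spline view of the same data:

```r
sfit <- fit_spline_model(pm, m = 3)
head(rr_curve(sfit, grid = seq(0, 20, 5)), 3)
#>    exposure       rr      lo95     hi95
#> 1:        0 1.000000 1.0000000 1.000000
#> 2:        5 1.052791 0.5957394 1.860492
#> 3:       10 1.141669 0.3973664 3.280115
```

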