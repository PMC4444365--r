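# oliverate

Population-dynamics analysis of olive fruit fly (*Bactrocera oleae*)
trap-monitoring time series, for entomologists and pest-monitoring
programs working with short (2–5 year) monthly series of sticky-trap
catches.

The package answers two questions about such series: how strongly is the
month-to-month rate of population change governed by density-dependent
feedback, and what do exogenous drivers — grove night temperature (nLST),
the North Atlantic Oscillation index (NAOi), and host-fruit availability —
add on top of it.

## The model

Trap rounds are pooled per site-month into flies/trap/day
(`FTD = Σ catch / Σ (traps × days)`), scaled to a monthly count and
log-transformed, `MFT_t = ln(FTD_t × days_t + 1)`. The per-capita rate of
change is the lag-1 log difference, `R_t = MFT_t − MFT_{t−1}`, and the core
model is the generalized least squares regression

```
R_t = a0 + a1·MFT_{t−1} + b·nLST_t + c·NAOi_t + d·fruit_t + ε_t,
ε ~ N(0, σ² D R D)
```

where `R` is the ARMA(p,q) correlation matrix at the true month
separations and `D` carries heteroscedastic weights (per-season/per-year
SD ratios, and/or variance proportional to nLST). `a1 < 0` is direct
negative density dependence. The error order and variance structure are
selected by ML/BIC with a parsimony tie-break and the winner refitted by
REML. Because the trap-derived `MFT` carries sampling error, the naive
estimate of `a1` is attenuated; a SIMEX analysis (λ ∈ {0.5,…,3}, 100
refits per λ, quadratic extrapolation to λ = −1) supplies the corrected
estimate with asymptotic and jackknife standard errors.

Everything upstream of the model is also provided: ACF, PACF and the
partial rate correlation function (PRCF — PACF of the detrended rate with
the lag-1 entry replaced by `cor(R_t, MFT_{t−1})`) for diagnosing the
order of feedback, linear trend tests, VIF collinearity screens, and a
synthetic-data generator that emulates the full data-generating process so
the pipeline validates itself by parameter recovery.

## Worked example

The numbered drivers under `analysis/` run the whole chain on a synthetic
60-month series and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diagnose.R
Rscript analysis/03_select_fit.R
Rscript analysis/04_simex.R
Rscript analysis/05_recovery.R
```

Stage 2 prints the diagnostics:

```
Rates: 59 usable month-to-month transitions
Trend in R_t: slope -0.0010, adj R^2 -0.017, p = 0.866 -> no temporal trend (stable rate of change)
PRCF lag 1 = -0.373 (95% bound +-0.255) -> negative first-order density dependence
```

— the rate of change is stable over time (no linear trend), and the lag-1
PRCF sits well outside the white-noise bound with a negative sign: months
that follow a high abundance tend to show a lower growth rate, the
classic signature of direct density dependence. Stage 4 then corrects the
regression estimate of that feedback for sampling error:

```
Naive a1 = -0.322; SIMEX-corrected a1 = -0.347 (asymptotic SE 0.092, jackknife SE 0.096)
```

The correction moves `a1` away from zero, as expected when measurement
error attenuates the naive fit (this series was generated with per-trap
sampling error SD 0.25 on the log scale). The same chain is available
programmatically:

```r
library(oliverate)
series <- gen_population(sim_config(n_months = 60, sigma_u = 0.25, seed = 2007))
rate   <- rate_of_change(series)
sel    <- select_model(rate, enumerate_candidates())   # 54 candidates, BIC
sel$fit_reml                                           # REML coefficients
simex_fit(rate, sigma_u = 0.25)                        # corrected a1
```

For field data, `read_series()` reads the monitoring CSV dialect
(`site,month,ftd,days,fruit,nlst,naoi`, month as `YYYY-MM`, empty cells =
missing) or raw trap rounds (`site,start,end,n_traps,catch`), and
`reproduce_field_analysis()` runs each site's published model structure
(see `field_site_specs()`) plus SIMEX over a multi-site file.

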