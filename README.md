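# stormlag

Case-crossover distributed-lag models for tropical cyclone exposure and
psychoactive drug-related mortality in county-month panels.

## What it does, and for whom

Environmental epidemiologists studying extreme-weather health effects need
to estimate how monthly, county-level death rates respond to cyclone
exposure — in the month of the storm and in the months after — without
confounding by everything that differs between counties or drifts over
decades. `stormlag` implements the full pipeline:

* **Exposure assembly** — daily maximum sustained winds at county
  population centers to monthly exposure-day counts (gale-to-violent
  34–63 kt, hurricane ≥ 64 kt), distributed-lag matrices, and June-anchored
  linear interpolation of annual populations to monthly offsets.
* **Outcome classification** — ICD-9/ICD-10 underlying-cause codes to the
  three-part psychoactive drug-related definition (overdose, mental and
  behavioral disorders due to psychoactive substance use, alcohol-induced),
  with an acute/chronic split and an editable code map.
* **The model** — a Bayesian conditional quasi-Poisson, time-stratified
  case-crossover fit with unconstrained distributed lags, two-period
  natural-spline trends, and a second-order random-walk temperature effect.
* **Post-processing** — percent change per exposure day, additional monthly
  deaths per million (DPM), credible-interval sign classification, subgroup
  contrasts, county disadvantage categories.
* **Sensitivity drivers** — alternative lag windows, leave-one-state-out,
  acute vs chronic subcauses, period restriction.
* **A synthetic panel generator** with planted effects, so everything is
  testable without restricted vital-statistics data.

## The model

Deaths \(Y_{it}\) in county \(i\), month \(t\) follow a Poisson model

\[\log \mu_{it} = \xi_{s(i,t)} + \sum_{\ell=0}^{L}\beta_\ell\, x_{i,t-\ell}
  + s(t) + f(\mathrm{temp}_{it}) + \log P_{it},\]

where the stratum \(s(i,t)\) is county \(i\)'s calendar month across study
years. Conditioning on stratum totals removes the intercepts \(\xi_s\)
exactly (within-stratum multinomial likelihood), adjusting by design for
all time-invariant county characteristics and seasonality. The
\(e^{\beta_\ell}\) are rate ratios per additional cyclone-exposed day
\(\ell\) months after exposure; \(s(t)\) is a piecewise natural-spline
trend with independent bases before/after a breakpoint (default December
2015); \(f\) is a binned temperature effect under an RW2 smoothness prior;
\(P_{it}\) is the interpolated monthly population. Overdispersion is
handled by tempering the posterior with the Pearson dispersion
(quasi-Poisson scaling). Inference is a Laplace-centred independence MCMC
sampler or a fast mode-plus-curvature approximation. See the methods
vignette (`vignettes/casecrossover-methods.Rmd`) for details and rationale.

## Worked example

```r
library(stormlag)

panel <- simulate_panel(sim_config(seed = 42))   # 30 counties, 2010-2019
panel
#> Synthetic county-month panel: 30 counties, 2010 - 2019
#>   exposed county-months: 433  total exposure days: 993
#>   total deaths: 16035
#>   planted lag log RR: 0.05, 0, 0, 0

fit <- fit_casecrossover(panel, model_config(seed = 42, chains = 2,
                                             draws = 500, warmup = 200))
summary(fit)
#> Case-crossover distributed-lag estimates (log RR per exposure day)
#>  lag    mean lower95 upper95 pct_change  ess
#>    0  0.0537  0.0349  0.0698       5.52  833
#>    1 -0.0034 -0.0233  0.0149      -0.34  922
#>    2  0.0036 -0.0159  0.0225       0.36  856
#>    3 -0.0153 -0.0343  0.0034      -1.52 1000
#> Pearson dispersion: 1.077
#> RW2 temperature precision (posterior mean): 536
#> Observations: 3501 ; strata: 360 ( 258 informative )
#> MH acceptance rate: 0.98

R0 <- baseline_dpm(panel, year = 2019)  # 35.9 deaths/month per million
effect_summary(fit, R0)
#>   group strength_class lag pct_mean pct_lo pct_hi dpm_mean dpm_lo dpm_hi    label
#> 1   all          total   0    5.522   3.55  7.232    1.981  1.273  2.595 positive
#> 2   all          total   1   -0.339  -2.30  1.506   -0.122 -0.827  0.540     null
#> 3   all          total   2    0.368  -1.57  2.270    0.132 -0.564  0.815     null
#> 4   all          total   3   -1.515  -3.37  0.342   -0.543 -1.209  0.123     null
```

Reading the output: the panel was generated with a planted lag-0 log rate
ratio of 0.05 (a 5.1% increase per exposure day) and no effect at later
lags. The fit recovers a 5.5% increase in the month of exposure with a 95%
credible interval excluding zero (classified `positive`), and null
associations at lags 1–3 — each additional exposed day in this panel adds
about 2.0 monthly deaths per million in the exposure month. Subgroup fits
(`fit_subgroup()` by age group, sex, subclass, or disadvantage category via
`categorize_disadvantage()`), contrasts (`subgroup_difference()`), and the
sensitivity drivers (`run_lag_window_grid()`, `leave_one_state_out()`,
`run_subcause()`, `restrict_period()`) all operate on the same panel.

Real data enter through the same file contract the generator writes
(`write_panel()` / `read_panel()`: plain CSV), or the component readers
(`count_exposure_days()` for daily winds, `aggregate_deaths()` for death
records with `default_codemap()`).

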