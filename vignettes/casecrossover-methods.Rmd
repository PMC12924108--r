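---
title: "Methods: a conditional quasi-Poisson case-crossover model for tropical cyclone exposure and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional quasi-Poisson case-crossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormlag)
```

## The scientific problem

Tropical cyclones disrupt communities for weeks to months: displacement,
psychological distress, interrupted health care and treatment access, and
destabilised drug supplies. `stormlag` estimates how county-level monthly
death rates from psychoactive drug-related causes (overdoses, substance-use
disorders, alcohol-induced disease) change per additional cyclone-exposed
day, in the month of exposure and in the months after.

The exposure unit is a *cyclone-exposed day*: a day on which a county's
population mean center experiences modelled sustained winds of at least 34
knots. Days are classed as gale-to-violent storm (34-63 kt) or hurricane
(>= 64 kt).

## The design and the model

### Time-stratified case-crossover conditioning

Death counts $Y_{it}$ for county $i$ and month $t$ are compared only within
a *stratum*: the set of that county's same calendar months across study
years (every September of county $i$, say). Conditioning on stratum totals
eliminates all time-invariant county characteristics and average
seasonality by design, rather than by covariate adjustment.

Formally, the underlying Poisson model is

$$Y_{it} \sim \text{Poisson}(\mu_{it}), \qquad
\log \mu_{it} = \xi_{s(i,t)} + \sum_{\ell=0}^{L} \beta_\ell x_{i,t-\ell}
 + s(t) + f(\text{temp}_{it}) + \log P_{it},$$

with stratum intercepts $\xi_s$, exposure-day counts $x_{i,t-\ell}$ at lags
$\ell = 0..L$ (default $L = 3$, unconstrained coefficients), a long-term
trend $s(t)$, a smooth temperature effect $f$, and a monthly population
offset $P_{it}$. Conditioning on the stratum totals removes $\xi_s$
exactly: within each stratum the member counts are multinomial with cell
log-odds given by the linear predictor, which is the likelihood
`fit_casecrossover()` maximises and samples. Each $e^{\beta_\ell}$ is the
rate ratio per additional exposure day $\ell$ months after exposure.

### Long-term trend

Drug-related death rates changed over the study period for reasons
unrelated to cyclones (prescribing patterns, the post-2015 shift in the
illicit opioid supply). The trend is modelled as *two fully separate*
natural cubic splines of the month index, split at a configurable
breakpoint (default December 2015), with no continuity constraint across
the breakpoint; a period-level indicator captures the jump. Within each
period, one internal knot is placed per three years (`knots_per_years`).
Because conditioning absorbs constants only within strata, the
between-period contrast remains identified.

### Temperature

Temperature affects both cyclone incidence and the physiology and
behaviour of drug use. The monthly mean temperature enters as a step
function over `temp_bins` (default 20) equal-width bins spanning the
observed range, with a second-order random-walk (RW2) smoothness prior on
the bin effects: the prior penalises second differences, so the fitted
curve is smooth without a fixed parametric shape. Identifiability against
the strata is ensured by a sum-to-zero contrast parameterisation plus a
weak ridge. The RW2 precision $\tau$ carries a weakly informative
Gamma(1, 0.01) hyperprior.

Numerical choices: temperatures at or beyond the binning range are
assigned to the boundary bins; an all-constant temperature series carries
no information and the term is dropped with a message (it would be
absorbed by the strata).

### Overdispersion: the quasi-Poisson choice

Monthly death counts are overdispersed relative to Poisson. The package
realises "quasi-Poisson" literally: the Pearson dispersion $\hat\varphi$
is estimated from the conditional fit
($X^2/\text{df}$ over cells in non-empty strata), and the posterior is the
conditional likelihood *tempered* by $1/\hat\varphi$. Point estimates are
those of the conditional fit; posterior spread is inflated by
$\hat\varphi$ — exactly the quasi-likelihood variance adjustment, carried
into the Bayesian formulation as a generalised posterior. We chose this
over a latent observation-level random effect because it matches the
quasi-Poisson estimating-equation behaviour directly, adds no
high-dimensional latent field to the posterior, and gives calibrated
intervals under negative-binomial data (verified by the coverage tests).
`overdispersion = "poisson"` disables the adjustment.

### Priors and the RW2 precision

Lag and trend coefficients get independent Normal(0, 10^2) priors
(effectively flat at the likelihood's scale; `prior_sd = Inf` gives truly
flat priors, used in the oracle tests). The Gamma hyperprior on $\tau$ is
conjugate to the RW2 Gaussian prior, so the mode search works with the
$\tau$-marginalised objective. For posterior sampling, $\tau$ is then fixed
at its marginal mode (an empirical-Bayes step): the joint
$(\alpha, \tau)$ geometry is a funnel that an independence sampler mixes
poorly over, while the lag coefficients — the quantities of scientific
interest — are insensitive to it. Conditional draws of $\tau$ given the
sampled bin effects are still reported so its uncertainty is visible.

### Inference modes

* `inference = "map_laplace"`: Newton ascent to the posterior mode, then a
  Gaussian (Laplace) approximation whose draws feed all summaries. Fast
  (sub-second at the reference scale); used for replicate studies.
* `inference = "mcmc"` (default): independence Metropolis-Hastings with
  the Laplace Gaussian as proposal, `chains` x `draws` kept draws after
  warmup. Because the conditional likelihood is close to Gaussian in the
  coefficients, acceptance rates are high (around 0.95 at the reference
  scale) and the two modes agree on the lag coefficients to well under
  0.01 on the log-RR scale (tested).

Every reported credible interval is the equal-tailed 2.5/97.5 percentile
interval of the draws; at least 1000 draws are required. Associations are
classified *positive* when the 95% CrI is entirely non-negative,
*negative* when entirely non-positive, and *null* otherwise.

### Degenerate inputs

A panel with no stratum in which exposure varies (and deaths occur) is not
identifiable under conditioning and the fit refuses with an explicit
error; so does a subgroup with no outcome events. Strata with a single
complete member, and county-months whose lag vectors would reach before
the series start, are excluded and counted in the fit's stratum
accounting. Non-informative strata (no exposure variation) are retained by
default — they still inform the trend and temperature terms — and can be
dropped with `drop_noninformative` for speed.

## Post-processing

Percent change per exposure day is $100(e^{\beta_\ell} - 1)$, summarised
over draws. Additional monthly deaths per million (DPM) multiply each
percent draw by $R_0/100$, where $R_0$ is a baseline age-standardised
monthly death rate per million; `baseline_dpm()` computes it from a panel
as the median county rate in a reference year, directly standardised over
the 15+ age groups (standard weights are an input, defaulting to the
panel's own age distribution). DPM is therefore proportional to the
percent scale at every summarised point, which the tests assert.

Subgroup contrasts pair index-aligned draws from two independently fitted
subgroups and summarise $\beta^A_\ell - \beta^B_\ell$; treating the two
posteriors as independent is exact for separate fits that share no
parameters. County disadvantage categories cross poverty and minority
percentages dichotomised at the medians of included counties; ties at the
median are "low" (the at-or-below side), a rule the output records.
Published cutpoints can be supplied instead of empirical medians.

## The synthetic panel generator

The generator exists so every pipeline stage is testable without
restricted vital-statistics data. It emulates, per county-month:

* sparse cyclone exposure confined to May-November, September modal, with
  day counts from a zero-truncated geometric (p = 0.45: median 2 days,
  long right tail, capped at days-in-month) and hurricane-force days as
  Bernoulli(0.045) per exposed day — matching the observed storm mix;
* overdispersed death counts: negative binomial with variance
  $\mu + \alpha\mu^2$ (default $\alpha = 0.2$), with a county intercept
  (SD 0.2), cosine seasonality (amplitude 0.1 on the log scale), a
  piecewise-linear trend kinked at December 2015 (slopes 0.04/0.10 per
  year), a mild U-shaped temperature effect, and the planted distributed
  lag effects (optionally sex-specific);
* demographic structure: five age groups x two sexes with realistic
  relative death-rate multipliers (normalised so the population-weighted
  mean is 1), county populations log-uniform on 20k-500k with small annual
  drift, annual counts interpolated to months by the same June-anchored
  rule the pipeline uses;
* three cause categories (overdose 58%, substance-use disorder 17%,
  alcohol-induced 25%) so subcause analyses have both subclasses.

The reference conditions are 30 counties over 2010-2019 with
`exposure_rate = 1.5` expected exposed months per county-year and baseline
rate 2e-5 deaths per person-month. The exposure rate emulates the
high-exposure coastal subset of cyclone-exposed counties rather than the
national average: at desk scale this keeps enough informative strata that
parameter-recovery studies are meaningful. All stages draw from
deterministic substreams of one master seed, so panels are bit-identical
under a fixed seed.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: spatially correlated wind fields and
storm tracks, migration and displacement after storms, reporting delays
and cause-of-death misclassification, and spatial correlation in death
rates beyond county intercepts. Tests on synthetic panels validate the
estimator's statistical correctness (bias, coverage, invariances), not the
substantive findings for any real population.

## Problem sizes used in validation

The replicate studies use the reference scale (30 counties x 10 years,
360 strata, about 3500 analysed county-months) with `map_laplace`
inference: 50 replicates for the bias/coverage test in the suite and 100
replicates in `scripts/acceptance.R`. At this scale a fit takes well under
a second; the Monte-Carlo error of a 100-replicate coverage estimate is
about 2 percentage points.

## Known limitations

* The spatial "borrowing of strength" available in fully spatial
  formulations is not implemented; county effects cancel by conditioning
  and no CAR term is fitted. The adjacency matrix is generated and carried
  so a spatial extension has its input.
* The dispersion estimate is a plug-in; its sampling noise is not
  propagated (a small undercoverage source at very sparse scales).
* Empirical-Bayes fixing of the RW2 precision understates the temperature
  curve's uncertainty (not the lag coefficients').
* The ICD code lists ship as an editable CSV following the NCHS
  drug-overdose and alcohol-induced definitions; users with a different
  registry convention should supply their own map, including the placement
  of alcohol-poisoning codes (X45/X65/Y15), which is exposed as a switch.
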