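---
title: "Methods: modelling an SSB tax's effect on adult obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling an SSB tax's effect on adult obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

## The model and its assumptions

`ssbtax` implements a comparative risk assessment of an ad valorem tax on
sugar-sweetened beverages (SSBs). The causal chain is deliberately simple
and runs entirely on aggregate quantities:

price rise → demand shift → energy-intake change → equilibrium weight
change → mean-BMI shift → counterfactual obesity prevalence.

The key structural assumptions are:

* **Demand.** One own-price elasticity for SSBs and three cross-price
  elasticities (milk, unsweetened fruit juice, diet drinks), applied
  identically to all ages and both sexes. No substitution to water, tea,
  coffee or solid food is modelled, and elasticities are not stratified by
  income.
* **Energy.** The percentage change in energy intake from each beverage
  equals the percentage change in its volume; beverage energy densities are
  fixed (1800 kJ/l SSB, 2540 kJ/l full-cream milk, 1340 kJ/l juice,
  4 kJ/l diet).
* **Weight.** The equilibrium energy-balance relation — a sustained
  94 kJ/day of intake per 1 kg of body weight — converts energy to weight.
  Only the new equilibrium is modelled, not the time path toward it; the
  model therefore says nothing about how fast the change is realised.
* **Prevalence.** Population BMI in each 5-year band and sex is summarised
  by a two-parameter positively skewed distribution (lognormal by default,
  gamma as an alternative). Obesity prevalence responds to the intervention
  only through a shift of the distribution's mean (the population-shift
  principle): individual-level heterogeneity in response is not modelled.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `tax_rate` | 0.20 | fraction | sensitivity range 0.10–0.30 |
| `pass_on_rate` | 1.00 | fraction | sensitivity range 0.80–1.20 |
| `elasticity_form` | `"power"` | — | `"linear"` available; see below |
| SSB own elasticity | −1.299 (SD 0.11) | — | Normal uncertainty |
| milk / juice / diet cross | 0.129 / 0.388 / −0.423 (SD 0.10/0.19/0.10) | — | Normal |
| energy densities | 1800 / 2540 / 1340 / 4 | kJ/l | fixed in MC |
| `kj_per_kg` | 94 (SD 2.96) | kJ/kg/day | Normal |
| serving volume | 330 | ml | tornado: 200/250/330/500 |
| cup volume | 250 | ml | with 500/125 ml caps |
| diet share of SSB | 0.04 | fraction | volume share |
| obesity threshold | 30 | kg/m² | 25 (overweight) available |
| heights | 1.693 m male, 1.601 f | m | flat across bands; overridable |

Baseline consumption (litres/person/day, six 10-year bands × four
beverages) carries the standard errors used by the Monte Carlo; each 5-year
model band inherits its decade's estimate, which is why adjacent bands share
energy results.

### Why the constant-elasticity (power) demand form is the default

The elasticity's textbook reading ("a 10% price rise cuts consumption by
13%") is the linear form, and the package implements it. But pushing the
published baseline volumes through the linear form at a 20% price rise
overshoots the published per-band energy changes materially (the 25–34 row
gives about −62 kJ/day against a printed −43), while the constant-elasticity
form `(1+Δp)^ε − 1` lands within about 1% of every printed band. We
therefore default to the power form and document the linear one as a
first-order approximation; the two agree in the limit of small price
changes, which the demand tests assert.

A related observation: our Monte Carlo means sit slightly above the
deterministic chain (convexity of `(1+Δp)^ε` in `ε`), and they match the
published central values more closely than the deterministic run does —
consistent with those central values being Monte Carlo means themselves.
The slight scatter among published values for the four oldest bands, which
share identical inputs under decade mapping, points the same way.

## Consumption imputation rules

Milk and juice are surveyed as cups per day; categories are imputed at range
midpoints with one cup = 250 ml, capping ">2 cups" at 500 ml and
"<0.5 cup" at 125 ml ("<1 cup" is accepted as an alias of the latter,
since survey instruments print both phrasings). SSBs are surveyed as times
drunk last week; weekly categories are imputed at midpoints 2 and 5, scaled
by serving/7, and "every day" is exactly one serving. "Don't know" is
treated as missing and excluded from numerator and denominator — imputing
zero would bias the means downward with no support in the instrument.
Diet-drink volume is pegged at 4% of SSB volume.

## Fitting the BMI distributions

Survey BMI records are cleaned by dropping values outside the weighted
1st–99th percentile range of the full adult sample (weighted percentiles use
the inverse-CDF convention). Each band × sex cell is then fitted by least
squares: the empirical weighted histogram (60 bins over 10–60 kg/m², both
configurable) is compared with the moment-matched lognormal or gamma density
at bin midpoints and the arithmetic mean and SD are optimised
(Nelder–Mead on log-parameters, started at the weighted sample moments).
Cells need at least 30 records. Fitted means and SDs are then smoothed
across age with least-squares polynomials (degree 3 for means, 2 for SDs by
default; the instrument behind the model said only "polynomial functions",
so the degrees are configurable and the smoothing can be switched off).

The counterfactual shift moves the arithmetic mean by ΔBMI while holding
the **arithmetic SD** fixed, which keeps reference and counterfactual
distributions visually comparable; a `hold = "sigma"` switch instead holds
the lognormal log-scale SD. Tail probabilities come from `plnorm`/`pgamma`
on the moment-converted parameters.

## Monte Carlo design

Each draw independently samples every uncertain quantity from its Normal
distribution: the four elasticities, the 94 kJ/kg/day factor, and the 24
consumption means (sampled at the 10-year level so decade-sharing bands move
together within a draw). Draws are untruncated — elasticities may cross
zero, which is what lets upper interval bounds of the older bands' energy
changes cross zero. Intervals are 2.5th/97.5th percentiles of the draws
(not a Normal approximation), with 10 000 draws by default. The sampling
order of quantities is fixed but permutable (`sample_order`), which the
tests use to confirm that only the distribution, not the stream allocation,
matters.

## Sensitivity analyses

The two-way grid reruns the deterministic chain over tax ∈ {10, 20, 30}% ×
pass-on ∈ {80…120}% and reports relative obesity change by sex; the
(20%, 100%) cell is asserted bit-identical to the main run. The serving-size
analysis exploits the fact that every imputed SSB volume is proportional to
the serving volume: baseline SSB (and its 4% diet shadow) is rescaled by
`size/330` — or fully re-estimated from records when those are supplied,
which the tests show is equivalent — and the chain rerun for 200, 250, 330
and 500 ml. Serving-size effects are summarised per size as the
percentage-point difference from the 330 ml reference case, the comparison
the original sensitivity claim is phrased in; on the calibrated baseline the
largest difference in men stays within 0.6 percentage points.

## The synthetic-data generator

The generator emulates the *marginal* structure the model consumes, not the
surveys' sampling designs:

* BMI records per band × sex cell are lognormal with configured arithmetic
  moments; cell sizes follow the population pyramid (largest-remainder
  allocation); heights are Normal per sex and independent of BMI (the model
  only ever uses a per-cell average height, so the correlation is
  irrelevant downstream); survey weights are 1 by default or gamma with
  mean 1 to exercise the weighted estimators.
* Consumption categories are drawn per decade band from probability vectors
  calibrated in closed form so the midpoint-imputed mean equals a target
  (interior categories held at fixed shares, top category solved against
  "none", 2% "don't know"). The default targets are the published baseline
  volumes.
* The default pyramid declines monotonically with age at SA-like magnitudes,
  and the default BMI profiles are calibrated so the pyramid-weighted
  baseline obesity prevalence is 13.2% in men and 33.3% in women — the
  values implied by the headline absolute (0.5/0.8 pp) and relative
  (3.8%/2.4%) changes.

What passing tests do show: the estimators recover the generator's
parameters (consumption means to sampling error; distribution fits to 1–2%
at n = 50 000), the chain reproduces the published energy table from
printed inputs, and every invariant (null-tax zeros, monotonicities,
permutation invariances) holds. What they do not show: behaviour under real
survey features the generator omits — cluster/stratum design effects,
within-person reporting error, BMI–height correlation, non-lognormal tails —
so real-microdata prevalence results are reproduced in structure, not value.

## Numerical choices and degenerate inputs

* Weighted percentile = smallest value whose cumulative weight share reaches
  the probability; with unit weights and 1 000 uniform records the 1–99%
  trim keeps 981.
* Histogram fitting error is reported as the raw sum of squared density
  deviations (`residual`), comparable across families on the same cell.
* `optim` failures raise an error carrying the cell size and start values
  rather than returning a half-converged fit.
* Zero tax or zero pass-on short-circuits nothing: the chain runs and all
  deltas are exactly zero, deterministically and in every MC draw.
* A shifted mean ≤ 0 kg/m² (possible only under absurd energy deltas) is a
  domain error in the deterministic chain; MC draws clamp the shifted mean
  at a tiny positive floor instead, so a single extreme draw cannot abort
  an uncertainty run.
* Polynomial smoothing requires degree < number of bands; degree 0 returns
  the grand mean.

## Problem sizes used by the test-suite

Distribution-fit recovery runs at n = 50 000 records; consumption-mean
recovery at n = 20 000 respondents; Monte Carlo checks at 500–10 000 draws
(10 000 for the interval reproduction, repeated over five seeds); the
pipeline smoke test at 12 000 records and 300 draws. These sizes make the
statistical tolerances comfortable while keeping the default suite quick.

## Known limitations

* Equilibrium-only: no weight-change dynamics, so cumulative impact over
  calendar time is understated for any horizon shorter than equilibrium.
* No energy compensation at later meals, no food-waste response, no
  concentrate/non-concentrate or income stratification of elasticities.
* The serving-size and pass-on analyses are deterministic by design; their
  uncertainty is not quantified.
* Real-survey design effects are out of scope; supplied survey weights are
  honoured by the estimators but the generator does not emulate clustering.
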