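---
title: "Methods: quantifying flowering-time extension across topographic aspects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying flowering-time extension across topographic aspects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topophen)
```

## The problem

Paired north- and south-facing slopes tens of metres apart differ in
insolation, and hence in soil temperature and moisture, by amounts
comparable to hundreds of metres of elevation. Because flowering tracks
temperature, the two aspects of a site flower out of phase: the warmer
south slope starts and ends earlier. When the two flowering windows only
partly overlap, a pollinator foraging over both slopes experiences a
longer season of floral resources than either slope provides alone.
`topophen` quantifies that extension from weekly inflorescence counts and
decomposes it into within-species (plastic/genotypic) and between-species
(turnover) components.

## Phenology metrics

For any entity (a plot, an aspect, a whole site, or one species on one
aspect) counts are pooled by survey date and turned into a cumulative
proportion of the season's total count. The start, midflowering and end
dates are the dates at which the cumulative proportion reaches 5%, 50%
and 95%; duration is end minus start. Two conventions are offered:

* **step** (default): the first survey date at or above the threshold —
  the date by which the threshold had been reached. Dates are then
  multiples of the survey interval.
* **interp**: linear interpolation between the bracketing surveys. This
  changes resolution, never the ordering of dates.

A species seen flowering on a single survey date gets a duration of
1 day rather than 0: flowering certainly lasted some positive time below
the survey's resolution. Entities with zero total count are flagged "no
flowering" and excluded downstream rather than raising errors.

## The extension statistic

With `Longer` the longer of the two single-aspect durations and
`Combined` the duration with both aspects available,

$$\mathrm{Extension} = \frac{\mathrm{Combined} - \mathrm{Longer}}{\mathrm{Longer}} \times 100.$$

This is conservative: it asks how much the *longer* slope is extended.
Two definitions of `Combined` are computed side by side:

* **pooled** (default): counts from both aspects' plots are pooled and
  the 5–95% window re-thresholded. This mirrors the cumulative-count
  definition of all other durations, but under strong abundance imbalance
  the pooled window can be *shorter* than the longer aspect's; such
  site-years are reported with a warning and never clamped.
* **union**: the measure of the union of the two aspect intervals, with
  any gap between them removed (a gap in time is not flowering time).
  Under this convention extension is non-negative by construction and,
  for two time-shifted copies of one community, equals the shift.

Aspect-level durations default to the mean of the aspect's three
plot-level durations (thresholds are defined per plot); pooling the
aspect's counts first is available as a switch. Yearly summary tables
average per-site values within year, and the tabled mean percentage is
the mean of per-site percentages — which is why it cannot be recomputed
from the tabled mean durations (the same convention produces the small
formula-vs-table percentage discrepancies the test suite documents).

At the species level the same union-with-gap-removal arithmetic applies
to each species present on both aspects of a site in a year, and
absolute turnover is the count of species present on exactly one aspect.
Restricting each site-year to its shared species and recomputing the
community extension isolates the within-species component; the
difference from the full-community value is attributed to turnover and
may legitimately be negative.

Complementarity — that the earlier-starting aspect also ends earlier —
is tested with an exact two-sided binomial sign test across site-years;
ties in either date are excluded and reported, a conservative choice the
data definition leaves open.

## Microclimate

Growing degree-days accumulate `max(0, daily mean − 5 °C)` per day;
daily means (not hourly integration) are the default because the choice
is not critical for a base far below spring means, and an hourly series
is averaged per day first anyway. Logger gaps longer than 7 days abort
the accumulation with a pointer to `gap_fill_temperature()`, which fills
each missing day with the same sensor's donor-year mean for that day,
shifted by the target-minus-donor air-temperature difference over the
gap day's month (the adjustment window is a package choice; any
reference series can be supplied). Moisture is log-transformed for
residual normality and the aspect contrast is tested by nested-model
comparison of fixed-effects models with site and measurement date
(categorical, nesting year) as covariates.

## Inference

All models are ordinary least squares with treatment-coded categorical
terms (reference level = first alphabetically). The Gaussian
log-likelihood uses the ML variance RSS/n. AICc counts the residual
variance as a parameter (`p = k + 1` with `k` regression coefficients),
the convention under which a year+site model over four years and four
sites has 8 df. Nested models are compared with the standard F ratio.
The marginal R² of a focal term is the variance of that term's
contribution to the fitted values over the response variance — an
all-fixed-effects analogue of the mixed-model marginal R²; we do not fit
random effects, and therefore report no conditional R².

## The synthetic landscape

The generator produces data with the statistical structure the analysis
assumes, so every stage is testable without field data. Calibrated
defaults:

| parameter | default | rationale |
|---|---|---|
| aspect soil-temperature offset | 3.06 °C | the field contrast between paired slopes |
| phenological sensitivity | 3.4 days/°C | advance of flowering per degree of March–May warming |
| turnover fraction | 0.3 | share of a site's species on one aspect only |
| curve sd | 7 d | species 5–95% window ≈ 23 d, matching species-level durations |
| species peak sd | 15 d | community 5–95% duration ≈ 3.29·√(15² + 7²) ≈ 54 d, matching community durations |
| abundance mean | 50 | expected inflorescences per species × plot × season |
| site / genotype / plot-noise sd | 3 / 2 / 2 d | plausible magnitudes; the field study reports no estimates, so these are calibration choices |
| year offsets | +0.5, +0.2, −0.9, +0.3 °C | interannual spread with the third year coolest |

Temperature is a seasonal sinusoid plus a diurnal cycle, site baseline,
year offset, half the aspect offset (±) and Gaussian reading noise
(sd 0.5 °C). Each species × plot × year peak is the pool peak plus site,
genotype and plot effects minus sensitivity × (plot March–May mean −
landscape mean); expected counts follow a discretised Gaussian
normalised over the weekly survey grid to the abundance mean (so
expected totals are conserved exactly) and are sampled as Poisson.
Zero-count records are retained so curves keep full support. Community
assembly — which species occur at a site and which are unique to one
aspect — is redrawn every year: the system this emulates is an annual
grassland that reassembles yearly, and presence and turnover are defined
per site-year throughout the analysis. A consequence is that in
community mode the genotype and plot-noise components are statistically
equivalent; the distinction matters in fixed-genotype mode, which zeroes
the genotype variance to emulate a sown common-genotype experiment in
which any aspect difference is pure plasticity.

What the generator does **not** emulate: skewed or multimodal flowering
curves, abundance differences among species, density dependence,
spatially explicit terrain or radiation, pollinator behaviour, and
year-to-year persistence of plot composition. Passing tests therefore
demonstrate that the estimators recover known structure of this
idealised landscape, not that field data meet these assumptions.

## Numerical and testing choices

* The midflowering-vs-temperature regression uses interpolated mid dates:
  step dates are quantised to the weekly grid, which inflates noise in a
  slope whose identifying contrast (≈ 3.4 × 3.06 ≈ 10.4 days) is not a
  grid multiple. Tabled phenology output keeps the step convention.
* The sensitivity-recovery check uses 5 sites × 4 years (120 plot-year
  observations, 20 paired site-years); the recovered slope is a
  stochastic quantity with a sampling sd near 0.2 days/°C under these
  conditions.
* Directional Monte-Carlo checks (full-community extension at least the
  shared-only extension in a majority of site-years) pool 160 simulated
  site-years so sampling noise cannot flip a true direction.
* The F-test type-I calibration uses 1000 null replicates at n = 30.
* Exact binomial p-values are validated against full 2ⁿ enumeration up
  to n = 12; threshold dates, interval unions and OLS coefficients
  against brute-force oracles.
* Degenerate inputs: zero-total curves are flagged, not errors; a
  constant regressor or aliased design raises an error naming the
  problem; `longer = 0` makes the extension percentage missing, with a
  message.

## Limitations

The pooled-count combined duration of two nearly Gaussian, equally
abundant curves grows slowly with their offset, so simulated community
extensions are modest and occasionally negative — the warning, not a
clamp, is deliberate. Field curves with heavier shoulders and uneven
abundances can yield larger extensions than the synthetic landscape
suggests. The analysis treats all effects as fixed; with many sites a
mixed-model formulation would be natural and would change the R²
decomposition.
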