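# topophen

Flowering-time extension across topographic aspects.

## The problem

In mid-latitude grasslands, paired north- and south-facing slopes less
than 100 m apart differ in soil temperature by about 3 °C — roughly the
climatic contrast of 500 m of elevation. Because flowering advances with
temperature (≈ 3.4 days per +1 °C of spring warming), the warm south
slope flowers earlier and the cool north slope later. Where the two
flowering windows only partly overlap, a pollinator foraging across both
slopes sees floral resources for longer than either slope offers alone.

`topophen` is for community ecologists and phenologists who want to
quantify that effect from weekly inflorescence surveys. It computes
cumulative flowering curves and 5/50/95 % threshold dates (start,
midflowering, end), the resource-extension statistic

```
Extension = (Combined − Longer) / Longer × 100
```

where `Longer` is the longer single-aspect flowering duration and
`Combined` the duration with both aspects available, and decomposes the
extension into within-species differences and species turnover
(`Turnover = # species unique to N + # species unique to S`). Supporting
stages cover the microclimate contrast (growing degree-days above 5 °C,
sign tests, logger gap-filling, soil-moisture models) and the classical
inference used throughout (fixed-effects OLS, AICc, nested-F model
comparison, exact binomial tests). A calibrated synthetic-landscape
generator makes the whole pipeline runnable and testable with no field
data.

## Worked example

```r
library(topophen)

# the published-style worked example: south 16.2 d, north 20.2 d,
# combined 25.6 d
extension_metrics(16.2, 20.2, 25.6)
#>   duration_south duration_north duration_combined longer extension_days extension_pct
#>             16.2           20.2              25.6   20.2            5.4          26.7

# a full synthetic landscape: 4 sites x 2 aspects x 3 plots, 2015-2018
land <- simulate_landscape(synthetic_config(seed = 42))

# community extension per site-year, averaged within year
ext <- community_extension(land$surveys)
extension_report(ext)
#>    year mean_south mean_north mean_combined mean_days_extension ...
#>    2015       57.8       56.0          61.2                2.33
#>    2016       54.8       57.8          61.2                3.50
#>    2017       51.3       55.4          56.0                0.00
#>    2018       49.6       50.2          56.0                1.75

# recovered phenological sensitivity (generator truth: -3.4 days/degC)
sens <- midflowering_regression(land$surveys, land$temperature)
round(c(slope = sens$slope, r2_temp = sens$r2_temp), 2)
#>   slope r2_temp
#>   -3.67    0.55
```

The first table reads: in 2015 the south slopes of a site flowered for
57.8 days on average and the north slopes 56.0; pooling both aspects
lengthened the flowering season to 61.2 days, an average extension of
2.33 days over the longer slope. The regression recovers the generating
temperature sensitivity (−3.4 days/°C) from the simulated surveys, with
temperature explaining about half the variance in midflowering dates.

`run_pipeline(synthetic_config(seed = 1), "out/")` executes every stage
(simulation, phenology summaries, extension and turnover decomposition,
microclimate, model comparison) and writes stage CSVs plus a plain-text
report; identical config and seed give byte-identical output. A thin
command-line wrapper with `simulate | metrics | extension |
microclimate | all` subcommands is installed at `inst/cli/topophen`.

See `vignettes/topophen-methods.Rmd` for the model, conventions
(threshold step vs interpolation, pooled vs union combined duration)
and the generator's calibration.

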