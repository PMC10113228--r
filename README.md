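# batgapm

Generalized additive Poisson models (GAPMs) for the spring emergence of
bats from subterranean hibernacula.

Hibernating bats are largely cut off from outside weather, yet their
spring emergence tracks it. This package implements, as a tested and
reusable pipeline, the statistical workflow for separating **extrinsic
(weather) triggers** of hourly flight activity at hibernaculum entrances
from **residual triggers** (everything the measured weather does not
explain, e.g. internal circannual timing): from raw light-barrier
entry/exit event streams and hourly weather tables to fitted models,
weather-independent activity curves, functional-group classification and
emergence timing/synchronization metrics. It is aimed at bat ecologists
and quantitative ecologists working with automated activity monitoring at
roosts.

## The model

Hourly movement counts per species are modelled as

```
Y_k ~ Poisson(mu_k),   log(mu_k) = alpha + site_k
      + beta1*T_S + beta2*T_A + beta3*AP + beta4*APT + beta5*WS + beta6*PR + beta7*CC
      + f1(ST) + f2(DOY) + f3(ST, DOY)
```

where `T_S`/`T_A` are soil (20 cm) and air temperature (deg C), `AP` air
pressure (hPa), `APT` the pressure trend (difference between the following
and preceding hour), `WS` wind speed (m/s), `PR` precipitation (mm), `CC`
cloud cover (eighths), `site` a factor for the hibernaculum, `ST` "sun
time" (sunset = 0, sunrise = -1/+1, linear in between) and `DOY` the day
of year (January 1st = day 0; the analysis window ends at day 136 in
mid-May). `f1`, `f2` are cyclic cubic regression splines (periodic up to
the second derivative), `f3` a main-effects-excluded tensor-product
interaction. The model is fitted by penalized iteratively reweighted least
squares with GCV-selected smoothing parameters — all spline and fitting
machinery is implemented in this package.

The response is the *smaller* of the 3-h-moving-averaged entry and exit
aggregates per hour, which damps one-way bulk movements; it is therefore a
non-negative real, and the Poisson deviance is used in its continuous
extension.

Downstream, `f2` evaluated alone is the **residual activity curve**:
species are ranked by its median absolute value, compared by
Kruskal-Wallis + pairwise Mann-Whitney tests (Bonferroni-corrected,
compact letter display) and labelled HRA/MRA/LRA (high/medium/low residual
activity). Activity-weighted quantiles of predicted daily activity give
the median emergence day and the IQR (synchronization) per species.

A seeded synthetic-data module (`simulate_weather()`,
`simulate_activity()`, `species_presets()`) generates weather, solar
events and event streams from the same generative equation — with the
published per-species coefficients as presets — so every stage is testable
against known truth.

## Worked example

```r
library(batgapm)

sites <- list(site_config("Mayen-Mauerstollen", 50.33, 7.22),
              site_config("Kaub", 50.08, 7.76))
truth <- species_presets("M.myotis")[[1]]

weather <- simulate_weather(sites, "2015-01-01", n_days = 137, seed = 1)
events  <- simulate_activity(truth, weather, sites, seed = 2,
                             species = "M.myotis")
frame   <- assemble_model_frame(aggregate_hourly(events), weather, sites)
fit     <- fit_gapm(frame, gapm_spec(reference_site = "Mayen-Mauerstollen"))
fit
#> Generalized additive Poisson activity model
#>   n = 6376 site-hours over 2 site(s), reference Mayen-Mauerstollen
#>   deviance explained: 0.914  (deviance 521.9, null 6057.5)
#>   smoothing parameters: f1=100, f2=1e+03, f3_st=1e+04, f3_doy=1e+10

subset(wald_tests(fit), term == "T_A")
#>   term  estimate         se        z            p stars
#> 4  T_A 0.2015838 0.01506992 13.37657 8.288472e-41   ***
```

The air-temperature coefficient 0.202 (SE 0.015) is consistent with the
generative value 0.173 (within two standard errors; the min-of-smoothed-
streams response deliberately transforms the raw counts, which mildly
shifts coefficients relative to a raw-count fit). Each extra degree
multiplies expected hourly activity by about
`exp(0.2) ~ 1.22`. `residual_activity(fit)` returns the centred DOY
partial effect; `emergence_summary(daily_predicted_activity(fit, frame),
residual_activity(fit))` reports the activity-weighted median day and IQR.

The full pipeline, driven by a YAML config (see
`inst/extdata/demo_config.yaml`), runs with

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "batgapm"))
```

and writes `events.csv`, `weather.csv`, `model_frame.csv`, `report.csv`
(coefficient table across species), per-species model bundles,
`curves.csv`, `groups.csv`, `emergence.csv`, `regressions.csv` and a
`log.txt` with full row-drop accounting. A thin CLI wrapper with
`simulate` / `preprocess` / `fit` / `residuals` / `emergence` / `run`
subcommands lives at `inst/cli/batgapm.R`.

### CSV schemas

* events: `timestamp` (ISO-8601 UTC), `site_id`, `species`, `direction`
  (`in`/`out`)
* weather: `site_id`, `timestamp`, `T_S`, `T_A`, `AP`, `WS`, `PR`, `CC`
  (a `dwd-like` reader dialect maps German weather-service column names
  and the -999 missing sentinel)
* model frame: response `y` plus all covariates, one row per site-hour

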