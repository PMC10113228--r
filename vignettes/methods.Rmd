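---
title: "Modelling spring emergence of hibernating bats: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring emergence of hibernating bats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batgapm)
```

## The problem

Automated light barriers at the entrances of subterranean hibernacula
record every bat movement (in or out) with a timestamp and a species
label. In spring, activity at these entrances mixes two kinds of
influence: the weather outside (which bats deep underground perceive only
indirectly) and everything else — internal circannual timing, hormonal
state, unmeasured cues. `batgapm` separates the two: it fits a
generalized additive Poisson model (GAPM) of hourly activity with linear
weather effects and periodic smooth terms, and treats the day-of-year
smooth, evaluated alone, as the *residual activity* — the part of the
seasonal pattern the measured weather does not explain.

## The model

For hourly movement counts $Y_k$ of one species,

$$Y_k \sim \mathrm{Poisson}(\mu_k), \qquad
\log \mu_k = \alpha + site_k + \beta_1 T_{S,k} + \beta_2 T_{A,k}
+ \beta_3 AP_k + \beta_4 APT_k + \beta_5 WS_k + \beta_6 PR_k + \beta_7 CC_k
+ f_1(ST_k) + f_2(DOY_k) + f_3(ST_k, DOY_k).$$

The covariates, with units:

| term | meaning | unit |
|------|---------|------|
| $T_S$ | soil temperature at 20 cm depth | °C |
| $T_A$ | air temperature | °C |
| $AP$  | air pressure at sea level | hPa |
| $APT$ | pressure trend, $AP_{t+1}-AP_{t-1}$ | hPa / 2 h |
| $WS$  | wind speed | m/s |
| $PR$  | precipitation | mm |
| $CC$  | cloud cover | eighths (0–8) |
| $ST$  | sun time: sunset 0, sunrise ±1, linear in between | — |
| $DOY$ | day of year, January 1st = 0; analysis window ends at day 136 | days |

The site enters as a treatment-coded factor (configurable reference
level), so site coefficients read as log-rate differences from the
reference hibernaculum.

### The response

The response for each hour is *not* the raw count: entries and exits are
counted separately per hour, each smoothed by a three-hour moving
average, and the **smaller** of the two smoothed aggregates is taken.
This damps one-way bulk movements (such as the final departure wave) and
retains back-and-forth flight activity. Two consequences shape the
implementation:

* the response is a non-negative real, so the fitting machinery uses the
  continuous extension of the Poisson deviance,
  $2\sum_k \left[y_k\log(y_k/\mu_k) - (y_k - \mu_k)\right]$ with
  $y\log y := 0$ at $y=0$ (a quasi-likelihood reading);
* the moving average is applied per contiguous block of recorded hours,
  so recording gaps do not bleed smoothed counts across outages. At block
  boundaries the window shrinks to the available terms rather than
  discarding the first and last hour of each block.

### Cyclic splines

$f_1$ and $f_2$ are cyclic cubic regression splines: natural cubic
interpolating splines whose value, first and second derivative match at
the two ends of the period (period 2 for $ST$; the $DOY$ smooth spans
$[0, 366]$, wrapping at the year boundary, because the seasonal effect is
an annual cycle — a config option wraps over the observed range instead).
The basis is value-parameterised: coefficients are function values at the
knots, knot second derivatives are the linear map $m = B^{-1} D\beta$
given by the cyclic continuity equations, and the wiggliness penalty is
the exact integrated squared second derivative $S = D^\top B^{-1} D$.
Knots sit at sample quantiles by default (uniform optional), with the
first knot at the period start. Basis dimensions default to 10 for $f_1$,
20 for $f_2$ and 5×5 marginals for $f_3$; none of these are statements
about the original analysis, which does not disclose its basis choices —
they are package defaults, exposed in `gapm_spec()`.

Each smooth carries a sum-to-zero constraint, applied as a null-space
reparameterisation (one column fewer, weighted column sums exactly zero),
which keeps the smooths identifiable next to the intercept. The
interaction $f_3$ is a tensor product of *constrained* margins (row-wise
Kronecker products), so it contains no marginal main effects and is
jointly identifiable next to $f_1 + f_2$; it carries two penalties, one
per margin direction.

### Fitting

Penalized IRLS maximizes the penalized Poisson log-likelihood, with step
halving on the penalized deviance as a safeguard against Newton overshoot
(without it, strongly peaked seasonal patterns can push early iterates to
numerically indefinite weighted cross-products). Convergence is declared
at a relative deviance change below $10^{-8}$ (at most 100 iterations);
the linear predictor is clamped to $[-30, 30]$ purely as overflow
protection. The coefficient covariance is the inverse of the penalized
information, and per-term effective degrees of freedom are the diagonal
of $(X^\top WX + S_\lambda)^{-1} X^\top WX$.

Each penalty block is normalised to unit Frobenius norm before smoothing
selection, so one log-spaced grid ($10^{-4}$–$10^{10}$) serves smooths
whose raw second-derivative penalties differ by orders of magnitude (the
DOY penalty, measured per day over a 366-day period, is numerically tiny
next to the sun-time penalty on a period of 2).

### Smoothing selection: why UBRE is the default

Smoothing parameters are chosen by coordinate descent over the grid (two
sweeps, two outer alternations with the IRLS weights frozen in between —
"performance iteration" — so each candidate costs one small Cholesky
solve and the whole search is deterministic). Two scores are offered:

* **UBRE** (default): $D(\lambda) + 2\,\mathrm{edf}(\lambda)$, the
  AIC-type unbiased-risk score at fixed Poisson scale 1, with the
  deviance evaluated on the actual fit implied by the working
  coefficients;
* **GCV**: $n\,RSS_w / (n - \mathrm{edf})^2$ on the working penalized
  least-squares problem.

The default matters for sparse species. A species that is absent for
months produces long all-zero stretches in which the likelihood is
essentially flat as $f_2 \to -\infty$; driving the curve down there wins
a small but nonzero deviance reduction at almost no GCV cost, because
GCV's degrees-of-freedom correction is multiplicative on a vanishing
residual base. In experiments with the sparsest species preset, GCV
selected the smallest grid value and the fitted DOY curve diverged to
±100 on the link scale. UBRE's additive $2\,\mathrm{edf}$ cost resists
this, and is also what the standard GAM software this class of analysis
is usually fitted with uses by default for known-scale Poisson models.
Both criteria remain available (`gapm_spec(method = )`), along with fixed
smoothing parameters. A boundary solution at a grid edge is warned about;
for genuinely null smooths the upper edge is the expected outcome.

### Inference

Parametric terms get Wald z-tests with stars at 0.05 / 0.01 / 0.001.
Smooth terms get a Wald-type chi-squared test: the quadratic form of the
smooth's coefficients against a rank-truncated pseudo-inverse of its
covariance block, with rank equal to the rounded effective degrees of
freedom (at least 1). This is a deliberate simplification — refined
randomized-df corrections exist but are out of scope — and it is
calibrated conservatively in our null simulations (about 1–3 rejections
per 100 null replicates at the 5% level). Deviance explained is
$1 - D/D_0$ against the intercept-only model.

## Residual activity, groups, timing

The residual activity curve is the $f_2$ partial effect on a day grid,
link scale, centred to mean zero over the grid, so zero means "explained
by the other terms". Species are ranked by the median of $|$curve$|$;
a Kruskal–Wallis omnibus test on the per-day absolute values is followed
by all pairwise Mann–Whitney tests with Bonferroni correction (raw $p$
times the number of pairs, capped at 1), a compact letter display built
greedily in rank order from the non-significant pairs, and HRA/MRA/LRA
tier labels assigned by rank thirds of the letter groups. Design choices
worth stating plainly:

* the per-day grid values are the test sample; they are serially
  correlated, so the tests are descriptive rather than strictly valid —
  a caveat shared with the analysis style this mirrors;
* "DOY alone" uses $f_2$ only by default; the $ST$-marginalised $f_3$
  can be added via `include_f3 = TRUE`, but an interaction involving sun
  time is arguably not a function of day of year alone;
* for near-zero-activity periods the curve is bounded below only by the
  penalty, so its absolute level there is weakly identified — compare
  curves between species rather than reading single values literally.

Timing metrics use full-model response-scale predictions summed per day.
The median emergence day and the IQR come from weighted quantiles with
the midpoint convention ($p_i = (\mathrm{cum}_i - w_i/2)/W$, linear
interpolation), so symmetric weight profiles yield their centre of
symmetry and a point mass yields that day with IQR 0. The IQR (days
containing the central 50% of activity) is the synchronization measure:
smaller = more synchronized. Quantile weights are model-predicted daily
activity by default (an option uses observed daily totals); whisker-style
outlier trimming is a display convention only and never enters the
quantiles. Cross-species OLS regressions relate median day, IQR and mean
residual activity; with a handful of species these are illustrative, and
both the signed mean residual (default) and the mean absolute residual
are reported.

## The synthetic-data generator

The generator exists so that every stage has ground truth. It emulates
the *structure* of the study inputs, not real climatology:

* **Weather**: air temperature = annual harmonic (mean 9 °C, amplitude
  9 °C, minimum mid-January) + diel harmonic (amplitude 4 °C, peak 14:00)
  + AR(1) noise; soil temperature at 20 cm = damped (2.5 °C), 45-day
  lagged annual cycle + a low-pass filter of the air anomaly (≈4-day time
  constant) + slow AR(1) noise; pressure = mean-reverting walk around
  1013 hPa; rain = two-state Markov spells with exponential amounts;
  cloud cover = latent AR(1) mapped to eighths. Amplitudes were chosen
  once so that pairwise covariate correlations stay below 0.5, matching
  the weakly collinear regime the analysis reports for its real
  covariates; with these defaults the spring-window correlations peak
  around 0.2 and the air–soil correlation over a full year is positive
  and well below 1. `noise_scale = 0` gives the purely deterministic
  component, which the tests exploit.
* **Solar events** come from the NOAA solar-position equations
  (fractional year → equation of time and declination → sunrise hour
  angle at zenith 90.833°), accurate to a few minutes — ample for
  assigning hours to the day/night cycle. Polar day/night is out of the
  supported domain and errors explicitly.
* **Activity**: hourly Poisson draws from the model equation itself,
  split into entries and exits by a Binomial draw (split fraction 0.5 by
  default — in/out asymmetry is not modelled), with event timestamps
  uniform within the hour (sub-hour placement is irrelevant after hourly
  aggregation). Hours with missing covariates are skipped and counted.
* **Presets** (`species_presets()`) carry the published per-species
  intercepts, site offsets and the seven weather coefficients as truth,
  so parameter-recovery studies are anchored to field-realistic values.
  The smooths, which the source reports only graphically, are stylised: a
  diel cycle $1.5\cos(\pi(ST-0.5))$ (night-active) and a Gaussian spring
  bump whose peak day follows each species' reported timing (days
  80–109) and whose amplitude follows its residual-activity tier; the
  sparsest species' amplitude was set so its simulated annual event total
  matches the published photo-count scale. Both smooth components are
  centred over their period at construction, matching the fitted smooths'
  identifiability convention.

What the generator does *not* emulate: real weather-station climatology,
within-night behavioural structure, observation error in species
identification, autocorrelated activity beyond what the covariates
induce. Passing tests therefore demonstrate that the pipeline recovers
truth *under the model's own assumptions*; they cannot certify behaviour
under the field data's unknown misspecifications.

## Simulation-study scales and numerical conventions

The test suite's simulation studies use: parameter recovery at ~19,700
site-hours (six sites × 140 days truncated at day 136) over 50
replicates; null calibration of the smooth test over 100 replicates at
~5,300 site-hours; functional-group recovery (one high, two medium,
three low residual-activity species) over 50 replicates and emergence
ordering (generative peaks at days 80/90/95/100/108/109) over 25
replicates at one site × 137 days each. These sizes give the studies
stable pass/fail behaviour while keeping a full run of the suite in the
minutes range. Parameter-recovery frames draw counts directly from the
generative rate (`simulate_frame()`), i.e. at the model level; the
event-level path through moving averages and the minimum response is
exercised end to end separately, because the minimum of two smoothed
streams is a deliberately transformed response whose scale differs from
the raw counts.

Other conventions: ties in quantile-based knot placement fall back to
uniform spacing; an all-zero response is refused with an explicit
boundary error (the intercept would sit at $-\infty$); reading events
rejects malformed rows with a counted warning; every dropped model-frame
row is accounted for by reason (beyond day 136, missing covariate —
including the two APT boundary hours per site series) so that input rows
always equal output rows plus logged drops. Per-species models include
only sites where the species has recorded activity, mirroring the
published per-species site inclusion and avoiding quasi-separated site
dummies. Species with fewer than 100 frame rows (configurable) are
skipped with a logged reason, an analogue of the original informal
data-sufficiency rule. All simulation is seeded; reruns of the pipeline
with the same configuration are byte-identical.

## Known limitations

* The smooth-term test is a plain Wald construction; its null behaviour
  is conservative rather than exact.
* Serial correlation in hourly activity beyond the covariates is not
  modelled (no GEE/autocorrelation corrections, no random effects, no
  overdispersion scale), matching the printed model.
* The residual-activity level during long zero-activity stretches is
  penalty-determined (see above).
* Weighted quantiles on strongly discrete daily distributions inherit
  the ±1-day resolution of the day grid.
* Year effects are deliberately absent from the model specification.
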