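---
title: "Methods: D-UVB climatology, CW-D-UVB exposure and the 25(OH)D linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D-UVB climatology, CW-D-UVB exposure and the 25(OH)D linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duvbclim)
```

## The problem

Cutaneous synthesis after sun exposure is the main source of vitamin D, and
only a narrow UVB band (290--315 nm, peaking near 295--298 nm) drives it.
The vitamin-D-effective dose (**D-UVB**, kJ/m²) is the surface irradiance
weighted by that action spectrum and integrated over the day. Because the
solar zenith angle (SZA) controls the atmospheric path length, D-UVB varies
enormously with season and latitude even across Europe's moderate 35--64° N
range, and monthly mean 25-hydroxyvitamin D (25(OH)D) in populations tracks
a lagged, smoothed transform of it.

`duvbclim` implements that chain end to end: a clear-sky spectral dose
simulator, the missing-data rules of satellite daily-dose records, the
day-of-year climatology and its summary statistics, the "vitamin D winter"
duration, the cumulative weighted exposure score (**CW-D-UVB**), and the
delta-versus-March regression linking monthly CW-D-UVB to published monthly
25(OH)D means. A packaged monthly climatology table for 46 European
capitals anchors the desk-reproducible statistics; the simulator generates
everything else with known ground truth.

## Solar geometry

Declination and the equation of time use the Spencer Fourier fits (about
0.3° accuracy); the zenith angle follows from
$\cos z = \sin\varphi\sin\delta + \cos\varphi\cos\delta\cos H$ with the
hour angle $H$ taken from longitude-corrected apparent solar time. All
computation is in UTC, and a day's dose is attributed to the UTC date of
its local solar noon. Sunrise and sunset are the SZA = 90° crossings,
solved by bisection to one-minute resolution; polar day and night return
explicit sentinels. Full ephemeris precision is deliberately not pursued:
the SZA plays a structural role (seasonal cycle, day length, the 78°
retrieval cutoff), not a metrological one. The test suite checks the
implementation against an independent Michalsky-style ephemeris to 0.5° on
a random grid.

## The clear-sky spectral model

The simulator is a deliberately simplified plane-parallel model, a
structural stand-in for the radiative transfer behind satellite dose
products. Weighted surface irradiance at zenith angle $z$ is

$$E(z) = \cos z \,(1 + 0.08\,\mathrm{km})(1 + 0.25\,A)
\int_{290}^{315} E_0(\lambda)\,
e^{-\left[\sigma_{O_3}(\lambda)\,\Omega + r\,\tau_R(\lambda)\right] m(z)}
\, w(\lambda)\, d\lambda,$$

with $E_0$ the extraterrestrial spectrum, $\sigma_{O_3}$ the ozone
cross-section per Dobson unit, $\Omega$ the total ozone column, $\tau_R$
the Rayleigh optical depth, $m(z)$ the Kasten--Young airmass, $w$ the
action spectrum, $A$ the surface albedo, and the trapezoid rule on a 1-nm
grid. The per-nm tables are smooth reconstructions of standard reference
shapes (anchor points interpolated to the grid); the ozone anchors use
cold-stratosphere (~228 K) Huggins-band values, which is where the
absorption actually happens. The action spectrum table normalises to a
maximum of 1 at 295--297 nm and falls below 0.01 by 315 nm; it can be
exported with `write_action_spectrum()`.

One numerical choice deserves emphasis. Treating Rayleigh scattering as
pure Beer--Lambert loss roughly halves UVB at mid latitudes and badly
flattens the latitude gradient, because scattered photons largely still
reach the ground as diffuse irradiance. Instead of a multiple-scattering
treatment the model scales the Rayleigh depth by a single factor
`rayleigh_scaling` (default 0.5), sitting between pure extinction (1) and
a transparent scattering atmosphere (0). This keeps the closed
Beer--Lambert form, preserves every monotonicity (in ozone, Rayleigh
depth, SZA, latitude) and restores a realistic south--north contrast (the
38° N / 64° N annual cumulative ratio exceeds 3).

The model's absolute scale remains roughly 50--70% of published satellite
D-UVB doses; nothing in the package asserts simulator output against
published values. All quantitative comparisons with the printed capital
climatology go through the packaged table, exactly as the analysis
scripts do.

Diurnal dose integrates $E(z(t))$ every 5 minutes from sunrise to sunset
(the default; refining to 1 minute moves the dose by < 0.5%) and
multiplies by the day's cloud modification factor. The dose is zero in
polar night; on midnight-sun days the full 24 h around solar noon are
integrated.

## Missing-data rules

Satellite daily-dose records have two characteristic gaps, and the package
applies the corresponding rules:

* **Blackout days** (no cloud retrieval): the dose is imputed with the
  mean of the same (month, day) in the other years of the record
  (`impute_blackouts()`). Feb 29 imputes only from other leap years.
  Because the substitute is the mean, the day-of-year mean over observed
  data is left exactly fixed — the suite asserts this equality at
  machine precision under 10% random blackouts. Measured values are never
  altered and the operation is idempotent.
* **High-latitude winter** (geostationary cloud retrieval fails when noon
  SZA > 78°): the dose is multiplied by a fixed mean cloud attenuation of
  0.7 (`apply_winter_cloud_factor()`). The rule is applied per day from
  the noon-SZA criterion, not from a country list; the criterion alone
  reproduces the published gap-day counts (about 105 days/year at
  Reykjavik's latitude, about 10 at Vilnius').

## Climatology and summary statistics

`build_climatology()` averages each of the 365 (month, day) pairs over the
available years, dropping leap days, so an 18-year record reduces to 365
day-entries with mean, SD and n. With a single year the SD is defined as 0
with a warning. Monthly statistics are the mean and SD *of the day-entries
within the month*; annual statistics are over all 365 day-entries, so the
cumulative annual dose equals 365 × annual mean exactly, and the
day-weighted inversion `annual_mean_from_monthly()`
($\sum_m \bar{d}_m n_m / 365$, non-leap month lengths) reproduces the
annual mean of its own monthly summary identically. Applied to the
packaged capital table, it reproduces the printed annual column within
±0.006 kJ/m² for all 46 capitals — the printed annual values are
day-weighted, not plain averages of the monthly column.

**Vitamin D winter** is the count of climatological days with mean dose
strictly below 1 kJ/m², the conventional threshold under which synthesis
is negligible; days exactly at the threshold count as synthesis days. The
duration is monotone non-decreasing in the threshold and, on simulator
output, monotone non-decreasing in latitude over the 35--64° N ladder.

Fold ratios are reported to two decimals; comparisons against printed
integers use nearest-integer rounding. Note that the familiar printed
seasonal contrasts are July/December ratios; for a few northern capitals
the absolute peak month is June, so `peak_trough_ratio()` (max/min) can
differ by one rounding unit from the July/December figure.

## CW-D-UVB

CW-D-UVB at date $t$ is the weighted sum of the 135 daily doses strictly
preceding $t$:
$CW(t) = \sum_{k=1}^{135} w(k-1)\, d(t-k)$, with $w(0) = 1$ and $w$
non-increasing, reflecting that recent exposure contributes more to the
current 25(OH)D level. The exact weight function used by earlier work is
not published as a formula, so the package ships two labelled
reconstructions selected by `make_weights()`:

* `linear_taper` (default): $w(k) = (L-k)/L$; the weight sum is exactly
  $(L+1)/2 = 68$ for $L = 135$;
* `exponential`: $w(k) = 0.5^{k/45}$, motivated by the 1--2 month
  25(OH)D half-life, truncated at the window.

Weights are deliberately not normalised to sum 1, so CW keeps kJ/m² units
at the hundreds scale used when quoting effects per 100 kJ/m². Both forms
satisfy the qualitative contract: the CW impulse response is the weight
vector itself, CW is linear and local to its window, and on a seasonal
cycle the CW peak lags the dose peak by 30--60 days while the normalised
day-to-day variance shrinks more than 20-fold. Dates whose 135-day
lookback is incomplete (start of record, unimputed gaps) are NA.

## The delta-versus-March linkage

Studies reporting mean 25(OH)D by calendar month are matched to the
monthly CW profile of the capital of their country (`resolve_city_cw()`
also accepts `average(city1,city2)` for territories between two covered
capitals). For each month the differences relative to March — typically
the 25(OH)D nadir — are formed on both axes, removing study-level
baselines; March itself is identically (0, 0) and excluded; studies
without a March record are rejected with a reason. Pairs are pooled
within a cohort class (A population-based, B disease, C laboratory) and
fit by OLS with intercept (`stats::lm`), unweighted by default (sample
sizes of the source studies can be passed as case weights). The slope is
reported per kJ/m² and per 100 kJ/m²; the p-value is the two-sided t-test
on the slope with n − 2 df; no multiple-testing adjustment across the
three pre-specified classes. The delta construction makes the slope
exactly invariant to constant shifts of either axis, and the intercept is
reported as a diagnostic (≈ 0 by construction). The suite checks the fit
against an independent normal-equations computation to 1e-10 relative.

## The synthetic generator and what it does (not) show

`scenario_config()` fixes the study conditions: 18 years (2004--2021); a
spring-peaked ozone cycle of 330 ± 40 DU; daily cloud factors drawn from
a Beta distribution rescaled to (0.2, 1] with mean 0.72, less
concentrated (more variable) where the clear-sky dose is larger, so
day-to-day dose varies most in summer when there is most to lose; 3%
blackout days; and a study spec of 8 population-based studies observing
all 12 months with a generative slope of 0.126 nmol/L per kJ/m² and a
residual SD of 8 nmol/L on monthly means — values a reader of the
seasonal 25(OH)D literature would call typical. Each location draws from
its own stream derived from the master seed, so adding a location never
perturbs the others, and a fixed seed makes the whole pipeline
byte-reproducible.

Passing tests on this generator demonstrate the *mechanics*: exact
imputation invariance, the CW lag and smoothing, the latitude gradients,
and recovery of a known regression slope within sampling error (95% CI
coverage calibrated over 200 replicates). They do not validate the
absolute dose scale against any satellite product, do not reproduce the
46-city medians (36-fold seasonal contrast, 126-day median winter) which
require the full multi-city extract, and do not reproduce the published
r² ≈ 0.79 of the population-based linkage, which depends on the true
spread of CW deltas across the contributing countries.

## Numerical choices and problem sizes

Bisection tolerance 60 s for sunrise/sunset; 5-min diurnal step; 1-nm
trapezoid in wavelength; SD of a single-year day defined 0 with warning;
strict `<` at the winter threshold; fold ratios with a zero trough
reported `Inf` with a warning; degenerate regressions (constant
predictor, < 2 points) are errors, and the two-point fit reports its
p-value as missing. The test suite and analysis scripts run the simulator
at 2--18 years and 5--15 minute steps depending on what the check needs;
the acceptance script uses the full 18-year, 4-capital default at the
5-minute step.

## Known limitations

The spectral model is single-scatter, two-extinction, with fixed albedo
and a scalar elevation enhancement: no aerosols or pollution, no
snow-albedo seasonality, no refraction or horizon effects, and an
absolute scale below the satellite product's. Cloud noise is i.i.d.
across days and locations (no weather persistence, no spatial
correlation). The linkage regression pools studies without random
effects, mirroring the single-slope-per-class convention of the seasonal
25(OH)D literature; inputs must already be in nmol/L.
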