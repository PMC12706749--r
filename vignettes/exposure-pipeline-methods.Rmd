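---
title: "Methods: from week-long schoolyard campaigns to comparable exposure metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from week-long schoolyard campaigns to comparable exposure metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolexposure)
```

## The measurement problem

Campaigns that characterize air and noise pollution across many urban
schools typically cannot monitor every site simultaneously: a handful of
instruments rotate through the schools on a rolling weekly schedule, so each
school contributes one week of minute-resolution PM2.5, black carbon (BC)
and sound-level data, measured at a different time of year. Three
methodological problems follow, and this package implements the standard
solution to each:

1. **Instrument calibration.** Low-cost continuous PM2.5 monitors drift and
   respond differently to different aerosol mixes; week-integrated
   gravimetric filter samples are the reference. In West African cities the
   bias flips with season: during the dry, dusty Harmattan the optical
   monitors underestimate (true correction factor above 1), outside it they
   overestimate (below 1).
2. **Temporal comparability.** A school measured in a clean week looks
   misleadingly clean. A fixed-site network running yearround provides a
   weekly temporal adjustment factor (TAF), and dividing the school's weekly
   mean by its week's TAF yields an annual-equivalent concentration.
3. **Exposure-relevant averaging.** Children are present on weekdays
   07:00–15:00; noise during schoolyard breaks is largely the children
   themselves. Clock masks restrict the metrics accordingly.

## Gravimetric reference and correction factors

A filter sample with mass gain $\Delta m$ (µg), mean flow $Q$ (l/min) and
runtime $t$ (min) gives the concentration $C = \Delta m / (Q\,t/1000)$ in
µg/m³. Samples qualify only if the pump ran for at least 75% of the week
(7560 of 10080 minutes, i.e. 5 of 7 days) and held flow within 10% of the
nominal 1 l/min; both boundaries are inclusive, and `qc_filter_sample()`
reports every failed rule.

The collocation correction factor is a ratio of means, not a regression
slope: $\mathrm{CF} = C_\text{gravimetric} / \overline{C}_\text{continuous}$,
so that after `apply_cf()` the continuous weekly mean is *set equal to* the
integrated sample. Schools whose filter fails QC are corrected with the
arithmetic mean CF of all valid collocations in the same season
(`seasonal_mean_cf()`), pooling the two seasons separately. BC is left
missing when the filter is invalid — there is no continuous BC channel to
fall back on.

BC itself is proxied by filter darkening through the standard black-smoke
absorption coefficient $a = (A/2V)\,\ln(R_0/R)$, with $A$ the collection
area, $V$ the sampled volume and $R_0, R$ the pre/post reflectances,
reported in units of $10^{-5}\,\mathrm{m}^{-1}$.

## Temporal adjustment

The TAF for week $w$ is the ratio of the across-site mean weekly
concentration to the across-site mean annual concentration, computed on
paired sites: a station missing that week is removed from both the
numerator and the denominator. Annual means default to the mean of a site's
available weekly means, which makes the equal-weight average of TAFs over a
complete network year exactly 1.

The adjustment divides: annual-equivalent $= C_\text{week} / \mathrm{TAF}_w$.
The direction is fixed by an identifiability argument — with
$\mathrm{TAF}_w$ defined as week-over-annual, division is the only choice
under which a school that tracks the city-wide temporal field recovers its
own annual mean, and the package's parameter-recovery tests check exactly
that invariant. The school-hours PM metric (weekday 07:00–15:00 mean of the
CF-corrected minutes, 2400 minutes over a full week) is adjusted by the
same weekly TAF before reporting.

## Noise metrics

All levels are A-weighted one-minute Leq values. The package computes

* `leq_wk()` — energy mean over the whole week:
  $10\log_{10}\big(\tfrac1n\sum 10^{L_i/10}\big)$;
* `l_day_school()` — the same over weekday school hours minus the two break
  windows 09:30–10:00 and 12:00–12:30 (2100 minutes per complete week);
* `break_delta()` — mean over school days of (break Leq − non-break school
  Leq), the size of the children's own contribution;
* `intermittency_ratio()` — per calendar day, minutes whose level strictly
  exceeds the day's Leq + 3 dBA are events, and the IR is the percentage of
  acoustic energy they carry. Days aggregate energy-weighted by default
  (pooled energy sums); an arithmetic mean across days is available via
  `aggregate = "mean"` because published IR summaries are ambiguous between
  the two. Minutes exactly at the cutoff are not events. The IR is invariant
  to uniform level shifts, since the cutoff and the energies shift together.

## Annoyance scoring

Each child answers, per source (road traffic, aircraft, industry,
business, neighbors), an 11-point numeric and a 5-point verbal annoyance
question in the ISO/TS 15666 style. The three highly-annoyed percentages
are: HA\_N (numeric 8–10), HA\_V (verbal "very"/"extremely") and HA\_VW
("extremely" in full, "very" weighted 0.4) — so HA\_VW ≤ HA\_V always.
Missing answers are dropped per metric, not per child.

`exposure_response()` pools HA\_N over respondents within 5 dBA bins of the
measured school level (bins half-open, anchored at multiples of the width
at or below the minimum level, so they partition the axis and are
reproducible), attaches binomial 95% CIs (normal approximation; exact
Clopper–Pearson for bins under 10 respondents, where the approximation is
poor), and fits an ordinary least-squares quadratic to the bin percentages
at the bin midpoints. Fitting to bin aggregates rather than respondent-level
data mirrors how such curves are reported; with one school per bin placed at
the midpoint the fit interpolates exactly, which the tests exploit.

## Covariates and guidelines

NDVI classes use the published bands — bare soil (≤ 0.1), sparse vegetation
(0.2–0.5), dense vegetation (0.6–0.9); the bands leave gaps, and values in
a gap go to the nearer class with a warning. Road proximity splits at an
inclusive 500 m; the SES median split sends ties above, keeping "below"
strictly below. PM2.5 guideline tiers use the WHO annual AQG of 5 µg/m³
with interim targets 10/15/25/35; school noise is compared strictly against
the 55 dBA Ghana EPA daytime standard for educational facilities.

## Determinant models

`fit_determinants()` fits a Gaussian generalized additive model of
ln(PM2.5), ln(BC) or the untransformed weekly Leq on district, road
distances, commercial activity, NDVI, SES, surface, school type and season,
plus thin-plate regression spline smooths of weekly temperature, relative
humidity and rain (smoothing by GCV, via mgcv). The natural log makes
pollutant coefficients read as approximate proportional changes. Reference
categories are the conventional baselines: district "other", commercial
"none", surface "unpaved", school type "private", season "non-Harmattan".
A meteorology variable with fewer than four distinct values cannot support
a smooth and enters linearly (or is dropped when constant), so in the
pure-linear limit the model reproduces OLS coefficients exactly — a test
pins this to 1e-6. Rank-deficient designs error naming the collinear
columns rather than silently dropping them. Pearson correlations
(`pearson_ci()`) use the Fisher z interval and the conventional strength
labels on |r|: weak < 0.3, moderate 0.3–0.5, strong > 0.5.

## The synthetic city

`generate_study()` builds a complete synthetic study whose generating
parameters are returned as ground truth, so every stage above is testable
by parameter recovery. Design choices, made once:

* **Temporal field.** Weekly multipliers are log-normal around a seasonal
  level, $f_w \propto \exp(1.1\,\mathbb{1}[w \in \text{Harmattan}] +
  \mathcal N(0, 0.5))$, normalized to mean 1 over the study weeks. The
  normalization makes the annual-equivalent target exactly identifiable;
  the boost and spread were chosen so an 18-week study spans roughly the
  0.39–4.67 weekly TAF range that characterizes the strong Harmattan
  seasonality of Accra-like cities.
* **Instrument bias** is purely multiplicative by season: continuous
  minutes are true concentration divided by the season's true CF (defaults
  1.12 Harmattan / 0.83 non-Harmattan) times unit-mean log-normal minute
  noise, while the filter mass is exactly true concentration × sampled
  volume — the generator is self-consistent, and recovery of the seasonal
  CFs to ±0.02 at ≥30 collocations is the calibration acceptance check.
* **Tracking noise.** A school's weekly mean deviates from annual × field
  by log-normal noise with σ = 0.08 (σ = 0.05 for fixed sites): schools
  follow the city-wide field imperfectly. Under these defaults the median
  absolute relative error of annual-equivalent PM2.5 sits near 6%,
  comfortably within the 10% recovery criterion, and shrinks to zero with
  the noise.
* **Sound** is a per-school base (48–62 dBA) with 3 dBA Gaussian minute
  jitter, Poisson loud events (default 6/h, +10 dBA — each event minute
  carries ten times the base energy, putting the generator's IR near the
  low-50s % that marks event-driven traffic/market noise), and a +0.7 dBA
  elevation during break windows.
* **Annoyance** responses are Bernoulli draws with
  $P(\text{HA}) = \operatorname{logit}^{-1}(-10.4 + 0.15\,L)$ for road
  traffic (≈ 10% at 55 dBA, ≈ 25% at 62 dBA) and fixed base rates for the
  other sources (neighbors 0.6, others ≤ 0.08). The verbal answer derives
  from the numeric one through fixed cut-points (0–1 / 2–4 / 5–6 / 7 /
  8–10 → categories 1–5), which guarantees the coherence of the three HA
  metrics that the tests assert.
* **Randomness.** One global integer seed; per-school and per-site
  sub-streams are derived deterministically from it, so identical
  configurations yield bit-identical studies.
* Within-week diurnal PM structure at schools is left flat: nothing in the
  pipeline depends on it, and leaving it out keeps the school-hours metric's
  ground truth trivially equal to the weekly mean.

What the generator does *not* emulate: spatial autocorrelation between
schools, real atmospheric chemistry or acoustic propagation, instrument
dropouts, or diurnal traffic cycles. Passing recovery tests therefore
demonstrates that the pipeline's arithmetic and statistical machinery are
correct under the stated error model — not that the error model captures
every feature of field data.

## Problem sizes and numerical choices

The test-suite and acceptance runs use studies of 50–90 schools over 10–18
weeks at full minute resolution (10080 minutes/week), and 50 replicate
model fits of 90 schools for the coverage check — sizes at which every
recovery criterion is already stable. Energy means of dB levels are
computed in double precision directly (no log-sum-exp guard is needed over
the physical 0–120 dBA range). Oracle comparisons for Leq and IR are pinned
at 1e-9 dB; exact-interpolation checks at 1e-6. Half-open minute-aligned
clock intervals avoid double counting at boundaries; the IR event rule is
strictly greater-than, so a constant series has IR 0 rather than an
arbitrary split.

## A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_schools = 90, weeks = 18, harmattan_weeks = 1:4, seed = 1)
st  <- generate_study(cfg, fixed_minutes = FALSE)

cal <- calibrate_campaign(st$bundle$filters, st$bundle$pm_continuous)
cal$seasonal_cf[["Harmattan"]]$value        # ~1.12
cal$seasonal_cf[["non-Harmattan"]]$value    # ~0.83

taf <- weekly_taf_table(st$bundle$network_pm)
range(taf$taf)                              # wide Harmattan-driven spread

noise <- dplyr::bind_rows(lapply(st$bundle$sound, noise_summary))
median(noise$l_day_school)
ha_numeric(st$bundle$surveys, "road_traffic")

fit <- fit_determinants(simulate_determinant_table(90, list(market = 0.3)),
                        "ln_pm25")
fit$coefficients
```

## Limitations

The package reproduces a measurement-and-analysis *procedure*; it does not
ship field data, and reported field results (medians, model coefficients)
are functions of the real city, not of this code. The annoyance instrument
is validated for adults, not children — scoring is faithful to the
definitions, but interpretation inherits that caveat. The determinant
models are exploratory associations, not causal estimates, and include no
spatial random effects.
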