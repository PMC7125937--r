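---
title: "Generalizing city heat-mortality risk functions and projecting attributable deaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizing city heat-mortality risk functions and projecting attributable deaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

## The problem and the model

Observed temperature–mortality exposure-response functions (ERFs) exist for
only a few large cities: curves of relative risk (RR) of all-cause death
versus daily mean temperature, normalized so RR = 1 at the optimal
(minimum-mortality) temperature OT. Projecting heat impacts beyond those
cities requires a way to transport the curves. The method implemented here
rests on one empirical observation: when each city's hot side is summarized
by a quadratic in the temperature excess `T = t − OT`,

\[ RR = 1 + a\,T^2 + b\,T, \qquad T \ge 0, \]

the fitted coefficients \(a\) and \(b\) vary approximately linearly with the
city's summer mean temperature (SMT, the June–August mean) — curves are
steeper in cooler climates. Regressing \(a\) and \(b\) on SMT and writing
each regression line in slope/x-intercept form gives the generalized
function

\[ RR = 1 + a_s\,(\mathrm{SMT} - a_i)\,T^2 + b_s\,(\mathrm{SMT} - b_i)\,T, \]

evaluable at any location where OT and SMT are known. OT is generalized as
the location's 84th-percentile daily temperature. The shipped primary
parameterization (`erf_preset("eq2_variantA")`) is
\((a_s, a_i, b_s, b_i) = (-0.0014, 30.9, 0.005, 26.7)\).

Two structural thresholds follow directly. For SMT below \(b_i\) = 26.7 °C
the linear coefficient is negative and the raw quadratic dips below 1 at
small \(T\); the evaluation therefore clamps RR to a lower bound of 1 (the
clamp count is reported in run metadata). For SMT above \(a_i\) = 30.9 °C the
quadratic coefficient turns negative and risk would eventually decline with
temperature; such cell-days are evaluated as-is but counted, since they are
rare in the climates of interest.

## Fitting choices

Two first-class fit variants are provided because the constant term can be
treated two ways. Variant A fits `rr = c + bT + aT²` with a free constant
and discards the offset `c − 1` (it is reported as a diagnostic); this is
the primary variant and reproduces the preset constants from noise-free
synthetic cities. Variant B forces the curve through RR = 1 at `T = 0` by
fitting `rr − 1 = bT + aT²` without a constant, matching the alternate
preset (−0.0011, 32.3, 0.0032, 26.6). Fits use only the hot side
(`T ≥ 0`): the generalized function is defined for temperatures above OT,
and cold-side behaviour is out of scope. The coefficient regressions are
unweighted ordinary least squares; with only ten cities they are
small-sample, which `loo_sensitivity()` quantifies by refitting with each
city left out and summarizing the slope spread.

## Converting risk to deaths

The daily baseline mortality rate is the annual all-cause rate multiplied
by the month's share of annual deaths and divided by the month's day count,
so daily rates integrate back to the annual rate exactly. Attributable
deaths per cell-day are `pop × rate × (RR − 1)`; the `RR − 1` attributable
fraction is the stated convention of the method this package implements, and
a config switch (`af_convention = "excess_over_rr"`) offers the conventional
`(RR − 1)/RR` for sensitivity runs. Results are reported as mean annual
averages over a decade, aggregated nationally, by state
(deaths/year per million persons), and over city grid boxes.

## Adaptation scenarios

Each scenario is a weighted set of engine runs over the future temperatures
differing only in which decade's OT and SMT fields are used:

| scenario         | OT field        | SMT field       | weights |
|------------------|-----------------|-----------------|---------|
| `none`           | reference       | reference       | 1       |
| `smt`            | reference       | future          | 1       |
| `lagged_ot`      | reference + future | reference    | ½, ½    |
| `both_lagged`    | reference + future | future       | ½, ½    |
| `both_nonlagged` | future          | future          | 1       |

"Adapting to SMT" keeps OT at reference values: adaptation changes the
curve's shape, not the threshold. The lagged average is applied to the death
totals of the two constituent runs — the response — rather than to the OT
field itself; averaging the fields instead is available as a sensitivity
variant (`average_fields = TRUE`) and gives slightly different results
because the engine is nonlinear in OT. The lag fraction defaults to ½
("people adjust to half the change in the daily distribution"); other values
are supported but depart from the reference method. In the combined lagged
scenario only OT is lagged; SMT adaptation is taken in full, since summer
means shift far less abruptly than the distribution's tail.

## Uncertainty bookkeeping

Two independent fractional error sources are tracked: the bias introduced by
the generalization itself, characterized as the mean absolute relative error
of the evaluation comparisons (14 % from the recent-past −7 % and
projected −21 % totals), and the 35 % uncertainty of the underlying city
ERFs and temperature projections, taken as a configured constant rather than
recomputed. They combine in quadrature to 38 %, and confidence intervals are
symmetric multiplicative bounds `central × (1 ± combined)` rounded to a
configurable granularity (nearest 1,000 deaths for national projections).
No Monte-Carlo propagation of coefficient uncertainty is attempted; the
method works with scalar fractions.

## The synthetic data and what it does (not) show

The generator emulates the statistical structure of the real inputs, not
their geography:

* **Daily temperatures** — per-cell annual mean (a latitude gradient spanning
  8 °C around a 16 °C domain mean), a sinusoidal seasonal cycle of amplitude
  10 °C peaking at day 196 (mid-July), AR(1) residuals (coefficient 0.7,
  stationary SD 3 °C) initialized from the stationary distribution, and a
  linear trend in °C/decade applied uniformly relative to a reference year.
  A 365-day no-leap calendar is used throughout (June 1 = day 152,
  August 31 = day 243). Default settings put per-cell JJA means in the
  18–32 °C band typical of the climates the generalization targets; the
  band check shifts with the trend for future decades.
* **City curves** — sampled at 0.1 °C increments from OT to OT + 10 °C from
  a known generating truth (the preset constants evaluated at the city's
  SMT) plus i.i.d. Gaussian RR noise, clamped to RR ≥ 0. Noise-free curves
  satisfy RR(OT) = 1 exactly, so parameter recovery is testable to
  machine-level precision.
* **Population** — uniform random cell weights converted to integers by
  largest-remainder apportionment, conserving the national total exactly.
* **Monthly mortality weights** — a cosine peaking mid-January with
  configurable winter excess (default 15 %); a stated stand-in, not a
  reconstruction of any observed series.

Because the warming trend is spatially and seasonally uniform, full
adaptation to the shifted temperature distribution cancels the warming
almost exactly; the residual change is then only the SMT-driven change of
curve shape, which is slightly negative under the primary constants. Real
climate projections warm extremes faster than means, leaving a small
positive residual instead. Passing tests therefore demonstrate the engine's
arithmetic, orderings and attenuation magnitudes — not the sign of that
last, near-zero residual on real fields. The generator also makes no attempt
at GCM spatial correlation structure, bias-correction artefacts, humidity
metrics, or coastlines.

## Numerical choices and degenerate inputs

Percentiles interpolate linearly between closest order statistics (the
"type 7" convention); the percentile and the OT reference period are
explicit configuration (defaults: 84, 2010–2019 reference, 2090–2099
future, computed decade-wise). Observed-curve lookup interpolates linearly
between the 0.1 °C samples, holds the last RR above the sampled range (and
counts such days), and returns 1 below OT. Curves with fewer than three
hot-side samples, all-equal temperatures, regressions with fewer than three
distinct SMTs, or a zero slope (undefined x-intercept) raise typed errors
rather than returning garbage. Population and rate inputs must be
nonnegative; grid mismatches name the offending dimension.

## Problem sizes

The shipped analyses and tests run on deliberately small domains chosen to
exercise every code path at interactive speed: a 20×20 grid for the
two-decade projection workflow (seconds), tiny 2–4-cell fixtures for the
hand-checkable oracles, and 200 replicates of the ten-city recovery
experiment at RR noise SD 0.01. The engine is vectorized over cell-days, so
continental 0.5° domains (~15,000 land cells, 10-year decades) remain
within ordinary workstation memory.

## Presentation

The package is organized as an analysis workflow — numbered stage scripts
under `analysis/` that narrate the study over the reusable functions in
`R/` — because the method is a sequence of analyses (fit, generalize,
evaluate, project) rather than a standalone tool; `run_pipeline()` plays
the orchestration role and the stage scripts are the command-line surface.

## Known limitations

City-level projections from the generalized function carry large biases
(tens of percent in either direction) even when ten-city totals agree to a
few percent; the leave-one-out slope spread of 20–40 % is the dominant
small-sample caveat. Cold-related mortality, age structure, cause-specific
rates, socio-economic adaptation drivers and spatially resolved population
projections (a single national factor per decade is supported) are out of
scope.
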