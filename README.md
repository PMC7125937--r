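# heatmort

Heat exposure is a major cause of avoidable premature death, but
epidemiological exposure-response functions (ERFs) — curves of relative risk
of death versus daily mean temperature — are only observed for a handful of
large cities. **heatmort** implements a generalization of city-level ERFs
that lets them be applied anywhere: each city's curve is summarized by a
quadratic in the temperature excess above the local optimal temperature, the
quadratic's coefficients are regressed on the city's summer mean
temperature, and the resulting generalized function is evaluated on gridded
daily temperature fields to project heat-attributable deaths under warming
scenarios, with explicit adaptation representations and quadrature
uncertainty propagation.

The package is aimed at environmental-health and climate-impact researchers
who want a tested, reproducible implementation of this projection chain —
including a synthetic-data module that emulates the statistical structure of
all required inputs (daily temperature grids with seasonal cycle, AR(1)
noise and a warming trend; gridded population; monthly mortality weighting;
city ERF curves with known generating truth), so everything runs and is
verifiable without external downloads.

## The model

For a location with optimal (minimum-mortality) temperature OT — taken to be
the 84th-percentile daily temperature — and summer (June–August) mean
temperature SMT, the relative risk of death on a day with mean temperature
`t` is, with `T = t − OT`:

    RR = 1                                              for T ≤ 0
    RR = max(1, 1 + a_s (SMT − a_i) T² + b_s (SMT − b_i) T)   for T > 0

The primary fitted parameterization (variant A, free-offset city fits) is

    RR = 1 − 0.0014 (SMT − 30.9) T² + 0.005 (SMT − 26.7) T

and an alternate (variant B, city fits forced through RR = 1 at T = 0) is
`RR = 1 − 0.0011 (SMT − 32.3) T² + 0.0032 (SMT − 26.6) T`. Heat-attributable
deaths for a cell-day are `population × daily baseline mortality × (RR − 1)`,
with the daily baseline rate given by the annual all-cause rate weighted by
monthly mortality shares. Adaptation scenarios control which decade's OT and
SMT fields feed the evaluation: *adapting to SMT* uses the future decade's
SMT (flatter curves as summers warm), *lagged adaptation to OT* averages the
baseline run and the fully-shifted-OT run (people adjust to half the
century's shift in the daily distribution), and both can be combined.
Independent fractional uncertainties are combined in quadrature and wrapped
symmetrically around central estimates.

## Worked example

Fit ten synthetic cities generated from known truth at the reference-city
SMTs and recover the generalized parameters:

```r
library(heatmort)
smts <- us_city_smt()
curves <- lapply(seq_along(smts), function(i)
  gen_city_erf(synthetic_city_spec(smt_true = smts[[i]],
                                   city_id = names(smts)[i])))
p <- regress_coefficients(lapply(curves, fit_city_polynomial, variant = "A"))
c(p$slope_a, p$xint_a, p$slope_b, p$xint_b)
#> [1] -0.0014 30.9000  0.0050 26.7000

relative_risk(30.7, ot = 25.7, smt = 25.7, params = erf_preset("eq2_variantA"))
#> [1] 1.157
```

The value 1.157 is the relative risk five degrees above the optimal
temperature in a city with SMT 25.7 °C: a 15.7 % excess risk of death on
such a day.

The full analysis workflow lives under `analysis/` and is run stage by
stage (`Rscript analysis/01_simulate.R` … `05_uncertainty.R`), writing its
tables to `results/`. The projection stage prints, for a 20×20 synthetic
domain warmed by ~4 °C:

```
Baseline (2010s) heat-attributable deaths: 675 per year
  none            future 3912/yr, increase +3237 (100% of no-adaptation)
  smt             future 2589/yr, increase +1914 (59% of no-adaptation)
  lagged_ot       future 2291/yr, increase +1616 (50% of no-adaptation)
  both_lagged     future 1596/yr, increase +921 (28% of no-adaptation)
  both_nonlagged  future 603/yr, increase -72 (-2% of no-adaptation)
```

i.e. either single adaptation retains roughly half of the no-adaptation
increase, and simultaneous adaptation to both the thresholds and the curve
shape essentially eliminates it.

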