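---
title: "Methods: chronologies, climate response and drought resilience indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronologies, climate response and drought resilience indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtring)
```

## The problem

Long-lived trees record drought stress in their annual rings. Given
cross-dated ring-width series (total, earlywood or latewood widths, mm)
from a stand, we want (i) a site chronology clean of age/size trends with
honest quality statistics, (ii) the monthly climate signal in that
chronology, and (iii) per-tree quantification of how individual trees
resisted, recovered from, and remained resilient to documented droughts —
the growth-level fingerprint of ecological stress memory. This package
implements that pipeline and a ground-truth simulator to validate it.

## Standardization model

A raw series `w_t` mixes a biological age/size trend with climate signal.
We model the trend as a smooth curve `f_t` and work with ratio indices
`x_t = w_t / f_t` (default), which are dimensionless, fluctuate around 1
for stationary growth, and preserve relative (percentage) anomalies — the
property the resilience ratios below rely on. Difference indices
`w_t − f_t` are available for users who prefer additive residuals.

### The frequency-cutoff spline

`f_t` is the natural cubic smoothing spline minimizing
`Σ (w_t − f_t)² + λ ∫ f″²`. Rather than choosing `λ` directly, we fix the
spline's *frequency response*: on a uniform yearly grid the smoother's
transfer function is

    A(ω) = 1 / (1 + 12 λ (1 − cos ω)² / (2 + cos ω)),  ω = 2π/period,

which we solve for `λ` so that `A = 0.5` at a 30-year period (both
tunable: `detrend_config(spline_wavelength, cutoff_response)`). Variance
at the cutoff wavelength is thus split equally between trend and index;
decadal-and-faster variation survives, century-scale trends do not. The
system is solved exactly with a banded Cholesky (Reinsch form), so the fit
is the spline itself, not an approximation; the test suite verifies the
response behaviorally — a period-30 sinusoid is attenuated to 0.50 ± 10%
amplitude and a period-300 sinusoid passes at ≥ 0.95 — on interior points
only, because edge bias is inherent to any smoother with natural boundary
conditions.

Numerical guards: fitted values are clamped to ≥ 0.001 mm before ratio
division; zero widths (locally absent rings, the Tucson `0` convention)
produce index 0 and are excluded from mean-sensitivity terms and from
pairwise correlations when shared by both series of a pair; all-zero
series are rejected.

### Chronology and quality statistics

The site chronology is the per-year Tukey biweight robust mean of the
indices (tuning constant `c = 9`, scale = median absolute deviation,
iterated to 1e-8). Degenerate cases: n ≤ 2 falls back to the arithmetic
mean; zero MAD returns the median — the limit of the biweight as the
scale shrinks, and the only choice consistent with a sample like
`{1, 1, 1, 1, 100}` averaging to 1.

Quality is summarized by mean sensitivity (MS), the mean pairwise
interseries correlation (Rbar), and the expressed population signal
`EPS = n·Rbar / (n·Rbar + 1 − Rbar)`. Rbar is computed over all series
pairs on each pair's own overlap (minimum 20 years) rather than a strict
common interval — the windowing rule is not dictated by the statistic, and
pairwise overlaps use all the data; the reported common period is the span
with sample depth ≥ 2. MS/Rbar/EPS refer to the *standard* (non-
prewhitened) chronology by default; whether published tables use standard
or residual chronologies is often unstated, and both are computable here.

### Prewhitening

Chronologies carry biological autocorrelation that inflates apparent
climate correlations. For climate work we therefore fit AR(p), p chosen
by AIC over 0..3 (Yule–Walker), to each index series and use residuals
re-centred to mean 1. Two deliberate scope rules: (a) order selection by
AIC retains a fixed ~20–25% chance of fitting p > 0 to white noise — the
suite freezes that measured behavior rather than an idealized rate; (b)
prewhitening applies **only** to the climate-correlation branch. The
resilience indicators are ratios of growth *levels*; AR residuals destroy
levels, so those indicators always use the standard indices.

## Climate response

The dendrochronological window runs from previous-year June (`pJun`) to
current-year September — 16 months spanning the moisture recharge and the
growth season that shape a northern-hemisphere ring. For each
(variable, month) the package reports the Pearson correlation with the
chronology and a case-bootstrap percentile CI: years are resampled with
replacement (the same resample applied to every column, preserving the
cross-month structure), `n_boot = 1000` by default, 95% percentile bounds,
significance = CI excludes zero. Case bootstrap (not moving-block) is
appropriate because the input is prewhitened; percentile (not BCa)
intervals keep the procedure assumption-light; no multiple-testing
correction is applied by default, matching per-month significance stars in
the field's response-function plots (a Bonferroni switch exists). Years
with any missing month inside the window drop only the affected response
year. Identical seeds give bit-identical CIs; the suite verifies the
nominal 5% type-I error to ± 2 points per month over 500 simulated
datasets.

## Resilience indicators

For tree-level index series `x` and candidate year `t`:

* resistance `Rt = x_t / mean(x_{t−2..t−1})` — performance during vs
  before the disturbance;
* recovery `Rc = mean(x_{t+1..t+2}) / x_t` — after vs during;
* resilience `Rs = mean(x_{t+1..t+2}) / mean(x_{t−2..t−1})` — after vs
  before; values below 1 mean the event's effect prevails.

The 2-year pre/post windows are configurable. A design point worth
flagging: the resilience formula is sometimes printed with `x_{t−1}` alone
in the denominator. With a 2-year pre mean, `Rs = Rt·Rc` holds as an exact
algebraic identity — internally consistent with the other two indicators —
so `PRE_MEAN` is the default and `LAG1` is retained as a faithful-to-print
option. Indicators are evaluated per tree for every eligible year of
1750–2022; years whose window leaves the series span, or with a
non-positive denominator, are skipped.

For each calendar event and tree, the decline phase runs from the event's
first year to the **latest** year attaining the event's minimum index
(ties resolved late, by definition of "latest minimum"); `Dt` is its
length in years. `Pre5` averages the 5 flanking years on each side of the
event (both flanks pooled — "before and after" describes the pre- and
post-stress states; a before-only reading is narrower and discards the
recovery side), excluding flank years that fall inside another calendar
event. `DecU = (Pre5 − Min)/Dt`; a negative value (event minimum above the
flank level) is kept and flagged rather than floored, so users can see
events a tree simply did not register. `DecU` inherits the scale of its
input — dimensionless on indices, mm on raw widths; indices are the
default since the events span three centuries of age trend.

Low-growth periods in a chronology are maximal runs of at least 2
consecutive years below `mean − k·SD` (long-term moments, `k = 1` by
default). Indicator distributions are summarized by a Gaussian KDE
(Silverman bandwidth, 512-point grid, data range ± 3 bandwidths) and the
adjusted Fisher–Pearson skewness `g1 √(n(n−1))/(n−2)`.

## The synthetic forest

The generator states a world in which every pipeline claim is checkable:

    width_t = age_t · exp(u_t) · d_t,   u_t = φ u_{t−1} + β z_t + ε_t

with `age_t` a negative-exponential age curve (1.5 mm initial, rate
0.004/yr — a slow-growing, shade-tolerant broadleaf), `ε ~ N(0, σ²)`
independent per tree (σ = 0.2), `φ = 0.3` persistence, `z_t` the
standardized growing-season (Jun–Sep) precipitation anomaly of a shared
simulated climate (β = 0.2, sized so interseries correlations land near
the 0.4–0.6 typical of a good broadleaf site), and `d_t` a shared drought
multiplier: `1 − δ` (δ = 0.4) during calendar events, relaxing linearly
to 1 over 2 post-event years — the stress-memory carryover. The drought
acts on the *level*, not the AR state, so event-year resistance targets
`1 − δ` exactly and parameter recovery is clean; widths are floored at
0.01 mm. The climate tables add seasonal cycles, noise, and drought-year
anomalies (−35% precipitation, +1.5 °C Tmax, depressed PDSI/SPEI6). All
randomness flows from one master seed via fixed per-tree and per-variable
offsets.

What a green test establishes: the estimators recover imposed truths
(δ, φ, EPS quality, type-I error) under lognormal AR(1) noise with a
shared signal. What it does not: real wood has juvenile anatomy,
missing/false rings, disturbance pulses, non-stationary climate
sensitivity and cross-tree noise correlation, none of which the generator
emulates — so green tests validate the *method implementation*, not any
field result.

## Parameter recovery checks, concretely

With 15 trees, single-year events, δ = 0.5, no carryover and σ = 0.1, the
suite requires the mean event-year `Rt` within 0.50 ± 0.05 and `Rc`
within 2.0 ± 0.2, with `Rs = Rt·Rc` to machine precision; β and φ are set
to 0 in that experiment because a shared climate dip in event years would
confound the climate sensitivity with δ — the point is to identify the
imposed reduction. Monotonicity (higher δ ⇒ lower `Rt`; carryover ⇒ lower
`Rc`) is asserted separately under the full model.

## Known limitations

* Cross-dating is assumed done; no COFECHA-style segment checks.
* Only Tucson decadal `.rwl` (both precision dialects) and plain CSV are
  read; no Heidelberg/TRiDaS.
* Correlation functions only — no regression-on-PC response functions, no
  moving windows.
* The spline's edge years are biased toward the data, as for any smoother;
  chronology ends should be read with the usual caution.
* Indicator densities pool per-tree records; they are descriptive, not a
  mixed-model inference of drivers.
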