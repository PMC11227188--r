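# droughtring

Tree-ring chronologies, bootstrap climate response, and drought
resistance/recovery/resilience indices for dendroecology.

## What it is for

Dendroecologists studying how trees weather recurrent drought need three
linked analyses from a set of cross-dated ring-width series (total ring,
earlywood, or latewood widths):

1. **Chronology construction.** Each raw series is standardized with a
   cubic smoothing spline whose amplitude frequency response is 50% at a
   30-year wavelength, giving dimensionless ring-width indices
   `RWI_t = w_t / f_t`; a site chronology is the per-year Tukey biweight
   robust mean, with quality statistics: mean sensitivity
   `MS = mean(|2(x_{t+1}-x_t)/(x_{t+1}+x_t)|)`, mean interseries
   correlation `Rbar`, and the expressed population signal
   `EPS = n·Rbar / (n·Rbar + 1 − Rbar)` (quality bar 0.85).
2. **Climate response.** Pearson correlations between the (prewhitened)
   chronology and monthly climate — precipitation, evapotranspiration,
   Tmax, Tmin, PDSI, SPEI6 — over the 16-month dendrochronological window
   from previous-year June (`pJun`) through current-year September, with
   case-bootstrap 95% percentile confidence intervals.
3. **Drought stress signal.** Per-tree, per-year Lloret-type indicators on
   growth levels: resistance `Rt = x_t / x̄_{t−2..t−1}`, recovery
   `Rc = x̄_{t+1..t+2} / x_t`, resilience `Rs = x̄_{t+1..t+2} / x̄_pre`
   (so `Rs = Rt·Rc`), evaluated 1750–2022 over a historical drought
   calendar; per-event decline rate `DecU = (Pre5 − Min)/Dt`, where `Pre5`
   is the mean index over the 5 flanking years on each side of the event,
   `Min` the event minimum, and `Dt` the years from event start to the
   latest minimum; plus Gaussian kernel densities and adjusted
   Fisher–Pearson skewness of each indicator.

A synthetic forest generator with known ground truth (negative-exponential
age trend × AR(1) lognormal noise × shared climate signal × multi-year
drought reduction with lagged recovery) makes every stage testable without
field data.

## Worked example

```r
library(droughtring)

f     <- simulate_forest(simulation_config(seed = 42))   # 15 trees, 1700-2022
idx   <- lapply(f$collection$series, standardize)        # 30-yr / 50% spline, ratio indices
chron <- build_chronology(idx)
chron
#> <chronology> [LATEWOOD] 1700-2022, 15 series; MS 0.177, Rbar 0.637, EPS 0.963

rec <- evaluate_resilience(idx)                          # per tree x year, 1750-2022
ev  <- rec[rec$year %in% default_drought_calendar()$start, ]
sprintf("event-year means: Rt = %.3f, Rc = %.3f, Rs = %.3f (n = %d)",
        mean(ev$Rt), mean(ev$Rc), mean(ev$Rs), nrow(ev))
#> "event-year means: Rt = 0.398, Rc = 1.073, Rs = 0.415 (n = 135)"

density_summary(rec$Rt, "Rt")
#> <density_summary> Rt: n = 4065, bw = 0.0570, skewness = 1.123

resp <- bootstrap_correlation(build_chronology(lapply(idx, prewhiten_ar)),
                              f$climate, n_boot = 1000, seed = 42)
head(resp[resp$significant, c("variable", "month", "r")])
#>  variable month         r
#>      Prec   Aug 0.6504176
#>      Prec   Jul 0.6099165
#>      Prec   Jun 0.5878294
```

Reading: in the first year of each simulated drought, growth drops to about
40% of the pre-drought level (`Rt ≈ 0.4`, the generator's 40% reduction
plus depressed growing-season rainfall), recovery is slowed by the 2-year
carryover (`Rc ≈ 1.1`), and the post-drought level stays below the
pre-drought level (`Rs < 1`: the event's effect prevails). The chronology
correlates most strongly with current-summer precipitation — the signal
the generator encodes. The right-skewed `Rt` density (skewness 1.1) mirrors
a minority of trees with high resistance.

Command-line use mirrors the R API:

```sh
Rscript -e 'droughtring::droughtring_cli()' simulate --out-dir data --seed 11
Rscript -e 'droughtring::droughtring_cli()' stats --rwl data/lw.rwl --out stats.json
Rscript -e 'droughtring::droughtring_cli()' climcorr --chron chron.csv \
    --climate data/prec.csv --var Prec --nboot 1000 --seed 42 --out resp.csv
```

`run_all(run_config(...))` (or the `run-all` subcommand) chains
simulate/load → detrend → statistics → climate response → resilience and
writes `chronology.csv`, `stats.json`, `response.csv`, `resilience.csv`,
`declines.csv` plus a config copy and log.

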