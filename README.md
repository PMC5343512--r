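# oceantoe

Time of emergence of climate-change signals in drivers of marine ecosystem
stress.

## The problem

Marine organisms are adapted to the seasonally extreme conditions they
already experience — the warmest month's temperature, the year's lowest pH,
oxygen concentration or food supply. A forced climate trend becomes
ecologically consequential once it pushes those **annual extrema** outside
the envelope of unforced natural variability, and the *speed* of that
transition bounds the time available for adaptation or migration. This
package implements, as a tested R pipeline, the multi-model analysis that
quantifies when and where that happens for four drivers — sea-surface
temperature (annual maxima), surface pH, vertically integrated primary
production and 200–600 m thermocline oxygen (annual minima) — under a
business-as-usual and a mitigation emissions pathway.

It is aimed at climate/ocean scientists who want the emergence statistics
themselves (trend fitting with autocorrelated errors, changepoint-style
signal-start detection, noise estimation from control runs, multi-model
aggregation) on gridded monthly model output, together with a synthetic
Earth-system-model generator that makes every stage verifiable against
closed-form ground truth.

## The method

Per grid cell, per model, per driver:

1. **Annual extrema** `Y_t` are extracted from monthly values of the
   conjoined historical (1860–2005) + scenario (2006–2100) run.
2. The **start of the climate-change signal** is the year the cumulative
   sum of dY/dt becomes persistently uni-directional through 2100.
3. From that start, the trend is fitted with the AR(1)-error model

   `Y_t = mu + omega * t + N_t`,  `N_t = phi * N_{t-1} + eps_t`,

   by exact maximum likelihood (generalized least squares profiled over
   `phi`).
4. **Natural variability** `sigma` is one standard deviation of annual
   extrema in a 100-year (detrended) preindustrial control segment.
5. The **time of emergence** is the first year with
   `|omega| * (year - start) > 2 * sigma` — a threshold exceeding 95% of
   normally distributed noise — and the **pace** is `ToE - start`. ToE
   beyond 2100 is excluded.
6. Across models: per-pixel median ToE (± 1 inter-model s.d.),
   multi-driver mosaics at query years, and cos-latitude area-weighted
   curves of the ocean fraction under multiple (>1) and quadruple (all 4)
   drivers, 1900–2100.

Assumption QC uses the Lilliefors test (Monte-Carlo calibrated) on control
extrema and on trend residuals, and the Breusch–Pagan test on residuals
against time.

## Worked example

The `analysis/` scripts run the study end to end on the shipped synthetic
four-driver world (three pseudo-models, coarse global grid, paired
business-as-usual and half-slope mitigation scenarios):

```sh
Rscript analysis/01_simulate_ensemble.R   # the world + ground truth
Rscript analysis/02_trend_fits.R          # per-pixel AR(1)-GLS trends
Rscript analysis/03_emergence_maps.R      # per-model start/ToE/pace maps
Rscript analysis/04_ensemble_multidriver.R
Rscript analysis/05_qc_checks.R
```

or equivalently, in R:

```r
library(oceantoe)
run <- run_emergence_pipeline(study_config(seed = 1), outdir = "results")
```

`04_ensemble_multidriver.R` prints:

```
Global median ToE (ensemble, area-weighted):
  rcp85: ph 1928 (+/- 8.6 yr), sst 2041 (+/- 6.8 yr), o2 2048 (+/- 10.4 yr), pp 2077 (+/- 6.2 yr)
  rcp45: ph 1965 (+/- 17.8 yr), sst 2080 (+/- 8.2 yr), o2 2083 (+/- 3.1 yr), pp 2092 (+/- 1.1 yr)
  rcp85 ocean under >1 driver: 44% by 2030, 83% by 2050; all 4: 47% by 2100
  rcp45 ocean under >1 driver: 2% by 2030, 9% by 2050; all 4: 1% by 2100
Mitigation delay of the 50%-of-ocean multi-driver point: 64 years
```

Reading these numbers: in the synthetic world pH emerges first (tiny
natural variability against a steady acidification ramp — a global median
emergence a century before the others), SST follows in the 2040s, then
thermocline oxygen, and primary production last (a weak trend inside large
variability). Halving every trend slope (mitigation) delays emergence at
every pixel and holds the multi-driver ocean fraction below the
business-as-usual curve in every year. Each printed quantity is backed by a
CSV under `results/` (`toe_*.csv`, `fractions_*.csv`, `mosaic_*.csv`,
`global_median_toe.csv`) plus a JSON manifest with the seed and a
configuration hash; reruns with the same configuration are bit-identical.

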