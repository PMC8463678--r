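# dendroiso

Tree-ring stable-isotope chronologies and climate reconstruction.

Subarctic larch lay down annually resolved carbon and oxygen isotope
ratios in their ring cellulose: δ¹³C tracks summer moisture (dry summers →
stomatal closure → enriched δ¹³C), δ¹⁸O tracks the source and circulation
of the water (e.g. the spring Arctic Oscillation). `dendroiso` turns
cross-dated per-tree isotope series into climate reconstructions spanning
many centuries, for dendroclimatologists and paleoclimate analysts:

* **Chronology building** — juvenile-period trimming (first 50 rings),
  equal-weight per-year means behind a ≥4-tree replication gate, sample
  depth and summary statistics.
* **Suess correction** — removal of the post-1850 atmospheric δ¹³C
  decline: `corrected(t) = raw(t) − (atm(t) − atm(1850))`, exactly
  invertible from the returned correction log.
* **Transfer functions** — monthly/seasonal correlation screening, then
  inverse calibration `Rec_t = a·I_t + b + ε_t` (climate regressed on the
  isotope proxy), with split-period verification statistics: Pearson r,
  reduction of error `RE = 1 − SSE/Σ(obs − mean_cal)²`, coefficient of
  efficiency `CE = 1 − SSE/Σ(obs − mean_ver)²` (CE ≤ RE), Durbin–Watson
  `DW = Σ(Δe)²/Σe²`, and the sign-agreement (Gleichläufigkeit) coefficient
  Ks; coefficient percentiles by residual bootstrap.
* **Reconstruction and extremes** — full-length reconstructions with 95%
  bands, Hamming-window smoothing (41/101 yr), ±2σ/±3σ extreme-year
  detection, period contrasts, and matching of cold extremes to a volcanic
  eruption catalog (VEI ≥ 4).
* **Pseudoproxy generator** — synthetic climate, atmospheric δ¹³C, and
  tree sets with fully recorded ground truth (42 overlapping trees over
  466–2009 CE by default), so the entire pipeline is testable without
  external data.

See `vignettes/dendroiso-methods.Rmd` for the models, defaults, and
design choices.

## Worked example

```r
library(dendroiso)
report <- run_pipeline(pipeline_config(seed = 1), verbose = FALSE)
print(report)
```

```
Isotope reconstruction pipeline report
  config hash 01806c7a, seed 1
d13C chronology: 1494 years (516-2009), depth 4-22
  mean -24.86, SD 0.856, SE 0.0221 (over retained years)
d18O chronology: 1494 years (516-2009), depth 4-22
  mean 21.93, SD 3.322, SE 0.0859 (over retained years)
July precipitation reconstruction: 1494 years (516-2009), mean 56.95 mm, SD 14.24 mm
  Verification (n = 21): r = 0.999, RE = 0.997, CE = 0.997, DW = 1.94, Ks = 1.00
May AO reconstruction: 1494 years, mean -0.05, SD 1.06
  Verification (n = 21): r = 1.000, RE = 1.000, CE = 1.000, DW = 1.99, Ks = 1.00
Extremes (|z| >= 2): 61 dry/wet, 78 AO; volcanic-matched cold years: 5
```

Reading this: 42 synthetic trees per isotope were trimmed and averaged
into 1494-year chronologies (sample depth 4–22 trees). The δ¹³C
chronology (mean −24.86‰, SD 0.86‰) was Suess-corrected and calibrated
against July precipitation over 1990–2009, verified on 1969–1989: RE and
CE near 1 mean the reconstruction beats both no-skill reference forecasts,
DW ≈ 2 means uncorrelated residuals, Ks = 1 means every year-to-year
change has the right sign. The reconstruction averages 56.95 mm of July
precipitation. 61 years breach ±2σ in the precipitation reconstruction;
5 cold (negative AO) extreme years fall within 0–3 years of a VEI ≥ 4
eruption.

```r
print(report$calibration$july_precip)
```

```
Calibration 1990-2009 / verification 1969-1989
Forward:  Verification (n = 21): r = 0.999, RE = 0.997, CE = 0.997, DW = 1.94, Ks = 1.00
Reverse:  Verification (n = 20): r = 0.996, RE = 0.994, CE = 0.991, DW = 1.66, Ks = 0.79
Final model (union period):
Transfer model: y = -356.6 -16.64*proxy
  r = -0.998, r2 = 0.997, RMSE = 0.764, n = 41 (1969-2009)
Coefficient 2.5/97.5 percentiles (residual bootstrap):
      intercept    proxy
2.5%  -363.2047 -16.9000
97.5% -349.0099 -16.3407
```

The fitted slope −16.64 mm/‰ recovers the generator's ground-truth slope
of −16.723 mm/‰ within its bootstrap percentile band.

The published transfer equations are also shipped as fixtures:

```r
m <- taimyr_models()$july_precip_d13c
apply_transfer(m, annual_series(2000, -24.0))$value
#> [1] 43.711
```

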