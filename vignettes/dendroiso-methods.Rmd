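---
title: "Isotope chronologies and climate reconstruction: models and methods"
author: "dendroiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope chronologies and climate reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroiso)
```

## The problem

Stable carbon and oxygen isotope ratios of tree-ring cellulose
(δ¹³C~cell~, δ¹⁸O~cell~) in subarctic larch record, respectively, summer
moisture conditions and large-scale atmospheric circulation. Given a set
of cross-dated per-tree isotope series, the pipeline in this package

1. removes each tree's juvenile period,
2. averages the trees into a replication-gated mean chronology,
3. removes the industrial-era atmospheric δ¹³C decline (Suess effect),
4. screens monthly climate correlations, fits a linear transfer function
   by inverse calibration, and verifies it on a withheld period,
5. reconstructs the climate variable over the full chronology with a 95%
   confidence band, and
6. smooths, detects ±2σ/±3σ extreme years, and matches cold extremes to a
   volcanic eruption catalog.

Because real multi-century isotope datasets are large laboratory products,
the package ships a pseudoproxy generator with known ground truth; every
stage is validated against that truth rather than against data the user
must download.

## Chronology model

Each tree series is an uninterrupted run of annual cellulose values. The
first 50 rings (by ring age from the pith when known, else from the series
start) are excluded as the juvenile period; the shape of juvenile isotope
trends is variable in practice, so exclusion rather than detrending is
used. The chronology is the equal-weight arithmetic mean across all trees
covering a year, reported only where at least `min_replication = 4` trees
remain; under-replicated years are dropped, never interpolated. Summary
statistics use the sample (n−1) SD convention throughout, with
SE = SD/√n over the years of the stated period.

Anomalies are expressed in σ units as z = (x − m)/s with m and s computed
over a reference period (the full chronology by default).

## Suess correction

Fossil-fuel combustion has lowered atmospheric δ¹³C since ~1850. The
correction subtracts, for every year t ≥ 1850,
the difference atm(t) − atm(1850) from the raw series; years before 1850
are untouched and no other industrial-era correction (e.g. physiological
CO₂ response) is applied. Missing atmospheric coverage is a hard error —
the record is annual and dense in practice, and silent interpolation would
hide data problems. The returned correction log makes the operation
exactly invertible.

## Transfer function and verification

Calibration is *inverse*: the climate variable is the dependent variable,

$$\mathrm{Rec}_t = a \cdot I_t + b + \varepsilon_t$$

fitted by OLS over the calibration window (`stats::lm`). The fitter
accepts one or several proxies, but the standard reconstruction path is
single-proxy. `residual_rmse` is the df-adjusted residual standard error;
the reconstruction's 95% band is the constant ±1.96·RMSE. Published
fixture equations (loadable with `taimyr_models()`) carry an additional
`extra_offset` of +0.15 preserved verbatim from their source; its origin
is not interpreted, and freshly fitted models set it to zero.

Verification on a window disjoint from calibration reports:

* Pearson r (two-sided p by the t transform where needed),
* RE = 1 − SSE/Σ(obs − mean~cal~)², skill against the calibration-period
  mean as the no-skill forecast,
* CE = 1 − SSE/Σ(obs − mean~ver~)², the stricter analogue (CE ≤ RE always,
  since the verification mean minimizes the denominator),
* DW = Σ(e~t~ − e~t−1~)²/Σe~t~² on verification residuals (range 0–4, 2 ≈
  no autocorrelation),
* Ks, the sign-agreement (Gleichläufigkeit) fraction of adjacent year
  pairs, with zero first-differences contributing ½.

`calibrate_full()` runs the split in both directions (calibration and
verification swapped), fits the final model on the union of both windows,
and reports 2.5/97.5 coefficient percentiles from a seeded residual
bootstrap (1000 resamples by default); the percentile construction is a
package choice, as is assigning a shared boundary year (1990) to the
calibration window only.

## Smoothing, extremes, volcanic matching

Low-frequency displays use a centered Hamming moving average with weights
w~k~ = 0.54 − 0.46·cos(2πk/(M−1)) normalized to sum to one (window 41 yr
for chronologies, 101 yr for long reconstructions). At the edges the
window is truncated and renormalized rather than padded, so no values are
fabricated beyond the series; positive convex weights guarantee the output
stays within the input's range.

Extreme years are those with |z| ≥ 2 against the full-period reference,
annotated when |z| ≥ 3. The sign is interpreted in the reconstruction's
own units (dry/wet for precipitation, negative/positive phase for the AO
index), not the raw isotope sign. Cold (negative-phase) extremes are
matched to eruptions with VEI ≥ 4 inside a configurable lag window,
0–3 years after the eruption by default — wide enough for delayed
radiative cooling, narrow enough not to claim decade-scale teleconnections.

## The pseudoproxy generator

`gen_climate()` draws, for each calendar month, a stationary AR(1) anomaly
process about a fixed subarctic monthly climatology (July mean temperature
12.6 °C, 280 mm annual precipitation with a July peak of 58 mm, zero-mean
AO index). Defaults: AR(1) coefficient 0.2, temperature innovation SD
1.5 °C, relative precipitation innovation SD 0.23 (giving July
precipitation SD ≈ 13–14 mm about 58 mm), AO innovation SD 1. In an
eruption year and the year after, temperatures are depressed by 1.5 °C and
the AO is shifted by −1.5 index units.

`gen_atm_record()` is constant at −6.4‰ before 1850 and declines
quadratically in time to −8.4‰ at 2009 — a smooth stand-in for the
ice-core/instrumental atmospheric record, with the correct plateau,
monotone decline, and total amplitude.

`gen_tree_series()` builds each tree as

value(t) = intercept + tree_offset + slope·A(t) + juvenile(age) +
suess(t) + noise(t)

with A(t) a monthly climate aggregate (July precipitation for δ¹³C, May AO
for δ¹⁸O), fixed N(0, tree_sd) offsets, a linear juvenile ramp decaying to
zero at ring age 50, the Suess term atm(t) − atm(1850) for carbon, and iid
N(0, 0.2‰) measurement noise matching analytical precision. Default
couplings are chosen for internal consistency with the published transfer
equations: δ¹³C slope −1/16.723 ‰ per mm with intercept −21.43 (so the
default chronology has mean ≈ −24.9‰ and SD ≈ 0.8‰), δ¹⁸O slope
1/0.320 ‰ per AO unit with intercept 22.11.

Lifespans are drawn from a clipped normal (mean 300 yr, SD 60, minimum
180). Placement is staggered: four trees are anchored at the range start,
a "living" fraction (20/42, mirroring typical living-tree sampling) ends
at the final year, the rest tile the interior; a deterministic greedy
repair pass then guarantees at least four trees per year *after* juvenile
trimming, from 50 years past the range start onwards. The default range
466–2009 therefore yields a chronology over exactly 516–2009 (1494
years). One master seed fans out to per-tree substreams so each tree's
draws are isolated; placement itself depends on the tree count.

### What the generator does and does not emulate

It reproduces the features the pipeline's statistics are sensitive to:
overlapping cohorts, replication structure, red-noise climate, an exact
Suess imprint, juvenile trends, between-tree offsets, and measurement
noise. It does **not** emulate spatial climate structure, month-to-month
correlation, non-climatic low-frequency proxy variance, or the weak
real-world proxy–climate coupling: synthetic calibration r is far higher
(≈0.99) than observed values (≈0.4–0.5), and the synthetic δ¹⁸O chronology
SD (~3‰) exceeds the observed ~1‰ for the same reason. Passing tests
therefore demonstrate correctness of the computations and recoverability
of known parameters, not field-strength skill estimates.

### A note on inverse-calibration bias

With a noisy proxy, regressing climate on proxy is an errors-in-variables
problem: the fitted slope is attenuated by the factor
s²·var(A)/(s²·var(A) + σ²~chronology~). Under the default conditions
(noise 0.2‰ per tree, modern sample depth ≈ 20) the attenuation is below
1%, and 95% CIs for the slope cover the truth in slightly above 90% of
replicates rather than the nominal 95% — the residual shortfall is this
bias, inherent to inverse calibration, not an implementation artifact.

## Problem sizes and numerical choices

The validation suite uses the full study geometry (42 trees, 1544 years,
100 replicates for recovery experiments; ~200 random series for
brute-force oracle comparisons at 1e−10 relative tolerance; 1000 random
pairs for the CE ≤ RE property). The bootstrap uses 1000 resamples in the
pipeline default and fewer in unit tests. Degenerate inputs fail loudly
with classed conditions: zero proxy variance, zero reference SD,
overlapping calibration/verification windows, non-contiguous series
passed to the smoother, under-replicated chronologies, and missing
atmospheric coverage are all errors, not warnings.

## Limitations

* Single-site, single-proxy-per-target design; no nested or
  principal-component multi-proxy reconstructions.
* The constant-width confidence band ignores proxy uncertainty and
  extrapolation beyond the calibration range.
* Extreme detection assumes approximate normality of the reference
  distribution when interpreting σ thresholds as rarity.
* Volcanic matching is association by time window, not attribution.
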