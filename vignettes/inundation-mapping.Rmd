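---
title: "Mapping wetland inundation from SWIR time series: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping wetland inundation from SWIR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inundatr)
```

## The problem and the model

Long-term wetland monitoring asks a deceptively simple question: how much
of a site was under water each year, and is that extent trending? Optical
satellites answer it through the short-wave infrared: water absorbs SWIR
radiation almost completely, so inundated pixels have reflectance well
below that of soil or vegetation. The difficulty is everything around that
physical fact — clouds, missing bands, radiometric drift between sensors
and years, and the absence of ground truth for three decades of history.

`inundatr` addresses each difficulty with a deliberately simple, fully
inspectable mechanism:

* **Annual median compositing.** All scenes from the June–September peak
  inundation season are reduced to one grid by the per-pixel median of
  valid observations. The median is robust to residual haze, undetected
  thin cloud and single-scene outliers in a way a mean is not.
* **Composite-specific thresholding.** Rather than one global cut-off, the
  threshold is recomputed per composite from reference regions that are
  permanently wet (open water that never drains) and permanently dry
  (barren or upland terrain that never floods):
  `threshold = swir_wet + c·(swir_dry − swir_wet)` with `c = 0.3`. Because
  both medians are recomputed each year, any radiometric transformation
  that is approximately affine — sensor changes, illumination, atmospheric
  scaling — cancels out of the classification entirely. This affine
  invariance is a tested property, not an aspiration.
* **Frequency and area aggregation.** Binary maps stack into per-pixel
  inundation frequencies and integrate into a yearly km² series.
* **Rank-based trend testing.** The Mann–Kendall test uses only the signs
  of pairwise differences, so it needs no distributional assumption about
  the areas and is invariant to monotone rescaling.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| threshold coefficient `c` | 0.3 | — | the standard choice in SWIR-threshold water mapping; placing the cut 3/10 of the way from wet to dry tolerates more spread in the (brighter, more heterogeneous) dry class |
| season window | Jun 1 – Sep 30 | dates | monsoon-driven peak inundation; both endpoints configurable |
| gap-fill window | ±366 days | days | "a year before or after" read inclusively; a leap-safe full year each way |
| `max_masked_fraction` | 0 | fraction | keep only composites devoid of masking; raise it (e.g. 0.01) for cloudy archives where strictness would discard most years |
| erosion margin | 1 | pixels | keeps reference regions clear of the fluctuating shoreline and of mixed boundary pixels |
| significance cut-off | 1.96 | `|Z_c|` | two-sided 5 % level of the standard normal |
| `pixel_area` | 0.0009 | km² | a 30 m Landsat pixel |
| validation design | 5 years × 50 points | — | 250 points per site, drawn uniformly over valid map pixels |

## What the synthetic generator emulates — and what it does not

The generator produces the statistical structure the pipeline assumes: a
water body whose true area follows a linear fractional trend
`A_y = A_0(1 + s·(y − y_0))` under multiplicative lognormal noise (unit
mean, coefficient of variation as configured, keeping areas positive); wet
and dry pixels drawn from truncated normal SWIR distributions; contiguous
cloud/shadow patches grown from random anchors to a target fraction;
scenes that lack the SWIR band entirely; and reference labels flipped at a
configured rate to emulate photo-interpretation error.

It deliberately does **not** model radiative transfer, sensor geometry,
terrain shadows, mixed boundary pixels, spatially correlated radiometric
drift, or realistic lake shapes — the water body is a disc, because
per-pixel thresholding is blind to shape. Consequently, passing tests show
that the *computational contracts* hold (masking, medians, thresholds,
trend statistics, accuracies are each exactly what they claim to be) and
that the pipeline recovers known truth under its own assumptions. They do
not certify accuracy on real imagery, where mixed pixels, vegetation-
covered water and shadowed terrain blur the wet/dry contrast; on real
data, validation against independent reference labels remains essential.

## Numerical choices and edge cases

* **Median convention.** Even-count medians are the mean of the two middle
  values, everywhere (gap-fill pools, composites, reference medians).
* **Ties at the threshold** are labelled dry: "below the threshold" is the
  inundated condition, and equality is resolved conservatively against
  detecting water.
* **Degenerate thresholds.** If the dry reference median does not exceed
  the wet one, the contrast has collapsed; classification refuses to run
  rather than silently invert the map (an override exists for forensic
  use).
* **Frequency denominators** are per-pixel available-year counts, so a
  pixel nodata in some years still reports a percentage on the years that
  exist, keeping the 0–100 contract exact.
* **Mann–Kendall small samples.** The normal approximation is used for all
  `n ≥ 3` with a warning below `n = 8`; exact tables are out of scope.
  Both the tie correction and the continuity correction are applied; with
  the continuity correction, `|S| ≤ 1` maps to `Z_c = 0`.
* **Autocorrelation** is screened (`|r1| > 1.96/√n`) and annotates the
  result; it does not modify the test by default, because no remedy is
  uniquely standard. Simple AR(1) pre-whitening is available behind a
  flag, off by default. Zero-variance series report `r1 = 0` with a
  degenerate flag.
* **Trends are computed on available years only.** Extending a monotone
  verdict to unobserved years is presentation, not computation; the result
  reports `n` so readers can weigh it.
* **Quartiles** use linear interpolation between order statistics
  (`quantile` type 7); the max/min extent ratio is flagged undefined when
  the minimum is zero rather than reported infinite. Ties for the year of
  minimum or maximum go to the earliest year.
* **Erosion at the image border** replicates edge pixels, so a reference
  region touching the grid edge is eroded only from its interior side.
* **Gap-fill candidate pools** are not restricted to the compositing
  season: any valid observation within ±366 days qualifies. Restricting to
  the season would shrink pools sharply at high cloud fractions; the
  median makes the wider pool safe for stable pixels, and boundary pixels
  that changed state between years are exactly the ones the residual
  per-year error budget (see below) accounts for.
* **Reference medians are computed on the final (gap-filled) composite**,
  the same grid that is classified, so threshold and classification always
  see identical values.
* **Validation points are drawn over valid map pixels only** (and
  independently, so coincident points are possible, as with uniform random
  points in any GIS); every drawn point is therefore usable, keeping the
  per-year design exactly at its nominal size.

## Design decisions that were genuinely open

* **Cloud patches are contiguous squares, not i.i.d. pixels.** Clustered
  masking is the regime that actually stresses gap-filling (whole
  neighbourhoods lost at once); the last patch is trimmed so the flagged
  count lands exactly on the target fraction, making the generator's
  contract sharp.
* **Area noise is multiplicative lognormal with unit mean** so that the
  configured trend slope remains the expected trend and areas stay
  positive. The noise parameter is interpreted as a coefficient of
  variation.
* **The error matrix is oriented rows = predicted, columns = reference**,
  which makes producer's accuracy a column quantity and user's accuracy a
  row quantity; every file output states this orientation in its headers.
* **Label noise on validation references is a free parameter.** Human
  photo-interpretation error has no agreed quantitative model; the default
  synthetic studies use 5 %, and the sensitivity is linear (expected
  overall accuracy ≈ 100·(1 − ε) when classification is otherwise exact).
* **Rasters are exchanged as ESRI ASCII grids** and regions as GeoJSON:
  plain-text, versionable, and readable by every GIS. Integer-scaled
  surface-reflectance products should be rescaled to 0–1 on ingest.

## Problem sizes used by the test suite

The contracts are exercised at sizes chosen to make every check exact and
fast: 5×5 constructed scenes for compositing conventions; grids up to
12×12 for the classifier-vs-oracle and affine-invariance sweeps; 200
random series of length 3–40 for the Mann–Kendall oracle; 500 null and 200
declining replicates of 30-year series for size and power; an exhaustive
enumeration of all 2×2 error matrices with at most 20 points; and two full
200×200-pixel, 30-year, 4-scenes-per-season end-to-end runs (noise-free
and 30 %-cloud). The batch scripts under `analysis/` use eight 60×60
sites over 1991–2020.

## Known limitations

* The generator's disc geometry cannot probe shape-dependent effects
  (shoreline length, fragmentation) — by construction none exist in
  per-pixel thresholding, but sub-pixel mixing along real shorelines is
  unmodelled.
* A single SWIR band is used; index-based methods (NDWI/MNDWI) and
  multi-class wetland typing are out of scope.
* Sen's slope magnitudes, seasonal Mann–Kendall variants and change-point
  detection are not provided; the trend machinery stops at the monotone
  verdict the survey design needs.
* Accuracy estimates are simple proportions; area-adjusted (stratified)
  estimators and kappa are intentionally omitted.
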