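# inundatr

Wetland surface-water mapping and trend analysis from short-wave infrared
(SWIR) reflectance time series, with a synthetic Landsat-like scene
generator so the entire pipeline can be developed, tested and audited
without downloading a single satellite scene.

The package is aimed at remote-sensing hydrologists and wetland ecologists
who track inundation extent over decades — the kind of multi-site survey
used to assess Ramsar-listed wetlands — and at anyone who needs a
transparent, fully scriptable reference implementation of the SWIR
thresholding workflow.

## The method

Water absorbs strongly in the short-wave infrared, so inundated pixels sit
low on the SWIR reflectance scale. For each year, the pipeline:

1. **Cloud-masks** every scene using its QA band and **gap-fills** masked
   pixels with the median of the same pixel's valid observations from
   scenes within ±366 days.
2. Builds the **annual median composite** over all June–September scenes
   (per-pixel median of valid values).
3. **Filters** composites that lack the SWIR band or retain residual
   masking beyond a configurable tolerance.
4. Computes a **composite-specific threshold** from permanent wet and dry
   reference regions:

   `SWIR_threshold = SWIR_wet + 0.3 (SWIR_dry − SWIR_wet)`

   where `SWIR_wet` and `SWIR_dry` are the median reflectances of the wet
   and dry reference pixels in that composite, and classifies pixels below
   the threshold as inundated (1), at or above as dry (0).
5. Aggregates maps into an **inundation-frequency grid** (percent of
   available years inundated per pixel) and a **yearly inundated-area
   series** (pixel counts × 0.0009 km² at 30 m).
6. Tests each series with the **Mann–Kendall test** — Kendall sum `S`,
   tie-corrected variance `Var(S) = [n(n−1)(2n+5) − Σ t_p(t_p−1)(2t_p+5)]/18`,
   continuity-corrected score `Z_c = (S − sign(S))/√Var(S)` — classifying
   trends as significantly increasing/decreasing when `|Z_c| > 1.96`
   (p < 0.05), after a lag-1 autocorrelation screen.
7. **Validates** each site with 50 seeded random points in each of 5
   random years (250 points) against reference labels, reporting the 2×2
   error matrix with overall, producer's and user's accuracies.

The synthetic generator (`site_truth_config()`, `generate_truth()`,
`render_scene_set()`) emulates the statistical structure this pipeline
assumes: a water body with a configurable interannual extent trend, wet and
dry SWIR distributions, contiguous cloud/shadow patches, scenes missing the
SWIR band, and photo-interpretation noise on reference labels.

## Worked example

A 60×60-pixel site (30 m pixels) observed 1991–2020, four scenes per
season, losing 2 % of its initial water area per year under 5 % area
noise, 20 % cloud cover and occasional missing SWIR bands:

```r
library(inundatr)
cfg <- site_truth_config(grid_rows = 60, grid_cols = 60, base_radius = 450,
  years = 1991:2020, area_trend_slope = -0.02, interannual_noise_sd = 0.05,
  cloud_fraction = 0.2, missing_band_prob = 0.05, label_noise_rate = 0.05,
  seed = 42)
report <- run_site(cfg, site_id = "demo", max_masked_fraction = 0.01)
print(report)
#> Inundation analysis for demo
#>   composites kept: 30  rejected: 0
#>   area: mean 0.449 km2, range 0.257-0.621 (min 2020, max 1991)
#>   Mann-Kendall: S = -404, Zc = -7.204, p = 5.843e-13 -> significantly_decreasing
#>   validation: 250 points, overall accuracy 93.6%
```

Every composite survived quality control (gap-filling repaired the cloud
damage), the area series runs from 0.621 km² in 1991 down to 0.257 km² in
2020, and the Mann–Kendall score `Z_c = −7.2` flags the injected decline as
significantly decreasing. The validation accuracy of 93.6 % reflects the
5 % reference-label noise plus a small residual classification error. The
1991 threshold illustrates the formula: wet median 0.0506, dry median
0.2502, giving `0.0506 + 0.3 × (0.2502 − 0.0506) = 0.1105`.

```r
print(report$error_matrix)
#> Error matrix (rows predicted, columns reference):
#>          reference
#> predicted dry wet
#>       dry 208  14
#>       wet   2  26
#> overall accuracy 93.6%; producer's dry 99.0% wet 65.0%; user's dry 93.7% wet 92.9%
```

## The analysis workflow

The `analysis/` scripts run the whole study on a batch of eight synthetic
sites spanning declining, stable and increasing regimes:

```sh
Rscript analysis/01_simulate_sites.R    # site configs + true areas
Rscript analysis/02_run_sites.R         # full pipeline per site
Rscript analysis/03_trend_summary.R     # trend table, class tally, elevation crosstab
Rscript analysis/04_accuracy_summary.R  # per-site and average accuracies
```

Summary tables land under `results/`; per-site intermediates (thresholds,
maps, frequency grids, validation points, reports) under `results/sites/`.

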