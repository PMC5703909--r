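# rodmetrics

Quantitative fluorescence image analysis for rod-shaped bacterial cells,
built for studies of subcellular organization — bactofilin scaffolds,
ParABS chromosome segregation, nucleoid architecture — in organisms like
*Myxococcus xanthus*.

Given multi-channel fluorescence images and a cell label mask, the
package computes, per cell and per population:

* **demographs** — per-cell axial intensity profiles stacked as rows
  sorted by cell length;
* **sub-pixel focus positions** (difference-of-Gaussians detection +
  2D Gaussian fitting) for diffraction-limited spots such as ParB·*parS*
  complexes;
* the **segregation symmetry coefficient**
  `S = D / (D + D2 − D1) × 100 %` (with `D = L − D1 − D2` the
  inter-focus distance and `D1 ≤ D2` the focus–pole distances) and the
  **normalized pole distance** `D_min = D1 / L × 100 %`; `S = 0 %` by
  definition for single-focus cells, and `S = 100 %` exactly for
  symmetric pairs;
* **axial extents** of patch-like and nucleoid signals with polarity
  classification (unipolar / bipolar / midcell / diffuse) and
  focus-to-nucleoid-edge distances;
* **per-cell Pearson colocalization** within masks, summarized as
  mean ± SD over cells;
* **population statistics** — box-plot quantiles with 5th/95th
  percentile whiskers and Mann–Whitney rank comparisons against a
  reference strain.

A first-class synthetic-field generator (`sim_config()`,
`simulate_field()`) renders spherocylindrical cells with configurable
foci, patches and nucleoids under Gaussian PSF blur, Poisson shot noise
and Gaussian read noise, emitting exact ground truth — every analysis
stage is validated by parameter recovery.

All user-facing functions take and return tibbles, so results chain
directly into dplyr/ggplot2 workflows; `autoplot()` methods render
demographs and strain comparisons, and test objects have broom-style
`tidy()`/`glance()` methods.

## Worked example

Simulate a wild-type-like field — symmetric ParB focus pairs placed
15–25 % of cell length from the poles, plus a half-length nucleoid — and
run the focus pipeline:

```r
library(rodmetrics)
library(dplyr)

cfg <- sim_config(
  n_cells = 40, field_shape = c(1024, 1024), seed = 17,
  channels = list(
    channel_spec("parb", "foci", amplitude = amplitude_for_snr(10),
                 rule = "symmetric_pair"),
    channel_spec("dapi", "nucleoid", amplitude = density_for_snr(10))))
field <- simulate_field(cfg)

geometry <- extract_geometry(field$mask, cfg$pixel_size)
foci <- detect_foci(field$channels$parb, field$mask, geometry,
                    focus_params(cfg$psf_sigma), "parb")
metrics <- compute_segregation_metrics(foci, geometry)
head(metrics, 3)
#> # A tibble: 3 × 9
#>   cell_id n_foci d1_um d2_um  d_um     S D_min length_um flag
#>     <int>  <int> <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl> <chr>
#> 1       1      2 0.852 0.875  2.60  99.1  19.7      4.33 <NA>
#> 2       2      2 0.702 0.711  3.42  99.8  14.5      4.83 <NA>
#> 3       3      2 1.84  1.85   6.80  99.9  17.6     10.5  <NA>
```

Each row is one cell: both foci were detected (`n_foci = 2`), the
focus–pole distances `d1_um`/`d2_um` are nearly equal, so `S` is close
to its symmetric-pair maximum of 100 %, and `D_min` falls in the
generative 15–25 % band. Population summaries follow the same
conventions:

```r
pop <- population_metrics(metrics)
boxplot_summary(pop$s_values$S)
#> # A tibble: 1 × 6
#>      p5   q25 median   q75   p95     n
#>   <dbl> <dbl>  <dbl> <dbl> <dbl> <int>
#> 1  98.8  99.4   99.7  99.8 100.0    40
```

The nucleoid fraction is recovered from the DAPI-like channel at its
generative value of 0.5:

```r
profiles <- extract_profiles(field$channels, field$mask, geometry)
bg <- estimate_background(field$channels$dapi, field$mask)
nuc <- measure_extents(filter(profiles, channel == "dapi"), background = bg)
boxplot_summary(nuc$fraction)
#> # A tibble: 1 × 6
#>      p5   q25 median   q75   p95     n
#>   <dbl> <dbl>  <dbl> <dbl> <dbl> <int>
#> 1 0.509 0.511  0.514 0.518 0.524    40
```

Demographs and strain comparisons plot via
`autoplot(build_demograph(orient_profile(profiles), channel = "dapi"))`
and `autoplot(compare_strains(...))`; see the vignette in `vignettes/`
for the full methods account.

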