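---
title: "Quantifying subcellular fluorescence in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular fluorescence in rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

```{r setup, message = FALSE}
library(rodmetrics)
library(dplyr)
```

## The measurement problem

In many rod-shaped bacteria, large protein assemblies occupy defined
subcellular territories: bactofilin scaffolds (BacNOP in *Myxococcus
xanthus*) form elongated subpolar patches of roughly 1–2 µm, the
chromosome-partitioning protein ParB condenses on centromere-like *parS*
sites into diffraction-limited foci held at a stereotyped distance from
the poles, and the nucleoid occupies a central region of the cell.
Quantifying such patterns from multi-channel widefield images reduces to
a handful of per-cell measurements on top of a common geometric frame:

* an **axial coordinate** `s` in [0, 1] along the cell's long axis,
  anchored at the two poles;
* per-cell **axial intensity profiles** and their population-level
  stacking into **demographs** (rows = cells sorted by length);
* **sub-pixel focus positions** and, from them, the segregation
  statistics `S` and `D_min`;
* **axial extents** of patch and nucleoid signals by thresholding
  profiles;
* **Pearson correlation** between channels within each cell mask as a
  colocalization score;
* population summaries: box-plot quantiles with 5th/95th-percentile
  whiskers and Mann–Whitney rank comparisons.

The package implements this pipeline on (image, label-mask) pairs and
ships a synthetic-field generator with exact ground truth, so that every
stage can be validated by parameter recovery rather than by eye.

## The segregation statistics

For a cell of length $L$ containing two ParB foci, let $D_1'$ be the
distance of the left focus (smaller $s$) from its pole, $D_2'$ that of
the right focus from the opposite pole, and $D = L - D_1' - D_2'$ the
inter-focus distance. After relabeling $D_1 = \min(D_1', D_2')$,
$D_2 = \max(D_1', D_2')$:

$$S = \frac{D}{D + D_2 - D_1} \times 100\%, \qquad
D_\min = \frac{D_1}{L} \times 100\%.$$

$S = 100\%$ exactly when the two foci are placed symmetrically
($D_1 = D_2$); by definition $S = 0\%$ for cells with a single focus.
Both statistics are invariant under mirror reflection of the cell and
under rescaling, which the test suite verifies property-style.

Two conventions required a decision the formulas do not make:

* **Pairing.** The left focus is paired with `pole_a`, the right with
  `pole_b`, before relabeling. This guarantees $D \ge 0$ and
  $S \le 100$ even when both foci sit in the same cell half, matching
  the plotted range of the statistic.
* **Degenerate cells.** Coincident foci give $D = 0$, the only way $S$
  could reach 0 for a two-focus cell; such cells are flagged and left
  undefined so that $S \in (0, 100]$ whenever it is defined. Cells with
  three or more foci have $S$ undefined (symmetry analyses consider
  two-focus cells only) and take $D_\min$ from the focus nearest a pole.

```{r}
compute_segregation_metrics(
  tibble(cell_id = 1L, s = c(0.1, 0.7)),   # foci at 1 and 7 µm
  tibble(cell_id = 1L, length_um = 10))
```

## The synthetic generator and what it emulates

`sim_config()` / `channel_spec()` describe a field of straight
spherocylindrical cells with per-channel signals; `sample_population()`
draws the ground truth and `render_field()` renders it: extended signals
(patch, nucleoid, uniform) as footprint regions at a photon density
convolved with a Gaussian PSF, foci as analytic Gaussians of known total
photon count, then background, Poisson shot noise and Gaussian read
noise. Defaults emulate 100×/1.4 NA imaging of *M. xanthus*-like cells:
65 nm pixels, PSF sigma 1.3 px, 0.7 µm cell width, lengths uniform on
3–12 µm, background 100 photons/px, read noise 2 photons. None of these
acquisition parameters is published for the experiments the pipeline is
modeled on, so they are package choices, fixed once; peak signal-to-noise
(peak above background over `sqrt(background)`) is the one knob the
validation suite varies, via `amplitude_for_snr()`.

Positional rules for foci mirror the biology being tested:
`polar_band(f_lo, f_hi)` places each focus independently at a fraction
`U(f_lo, f_hi)` of cell length from a random pole (the wild-type band is
0.15–0.25); `symmetric_pair` draws one band fraction `u` per cell and
mirrors the pair at `u` and `1 − u`, the literal reading of
"symmetrically arranged" origins after completed segregation;
`uniform_over_nucleoid` scatters foci uniformly over the cell's nucleoid
interval, emulating a segregation-defective strain. Nucleoid channels
occupy a configurable centered fraction of cell length (default 0.5)
with an optional per-cell DNA-content multiplier (`content_modes`,
`content_cv`) for 1N/2N mixtures.

What the generator deliberately does **not** reproduce: cell curvature
(all axial metrics are curvature-free by construction, so straight rods
keep the truth exact), division septa and time dynamics, 3D PSFs,
autofluorescence gradients, and realistic phase/DIC channels. Passing
recovery tests therefore demonstrates correctness of the measurement
code under the stated noise model, not robustness to every artifact of
real micrographs; on real data the label mask is an input and its
quality bounds everything downstream.

Cells are placed by rejection sampling with a 2-px dilation margin, so
footprints stay ≥ 4 px apart and PSF-blurred neighbors remain separable
by global thresholding — with a 1-px margin, blurred neighbors can merge
into one Otsu component. A field that cannot accommodate `n_cells` after
a bounded number of tries raises an error rather than silently packing
cells more densely.

## Geometry, profiles, demographs

`extract_geometry()` fits a straight principal-component axis per
labeled component; poles are the extreme pixel-center projections, and
`pole_a` is deterministically the pole with the smaller row (ties:
smaller column), so axial coordinates are reproducible before any
intensity-based orientation. A skeleton-based medial axis would handle
curved cells but is unnecessary for straight rods and harder to verify
exactly; it is a documented extension point. Near-isotropic components
are flagged `low_anisotropy` rather than dropped.

`extract_profile()` assigns every in-mask pixel to one of `n_bins`
(default 100) equal axial bins and averages; empty bins are linearly
interpolated and flagged, and a cell with fewer than `n_bins/2`
non-empty bins is an error rather than a silently coarse profile.
Normalized-length binning was chosen so all rows of a demograph share
columns; per-cell min–max normalization (constant rows map to 0) is the
default with raw intensities available. Orientation
(`brighter_half_first`) flips a cell iff the summed intensity of its
first axial half, over all channels, is below the second half — a
strict-inequality rule that is canonical (re-orienting a reversed
profile restores it) and never flips exact ties. The demograph itself is
just the length-sorted stack, shortest cell on top.

```{r, fig.height = 3}
fld <- simulate_field(sim_config(
  n_cells = 25, field_shape = c(768, 768), seed = 11,
  channels = channel_spec("patch", "patch",
                          amplitude = density_for_snr(10),
                          polarity = "bipolar")))
geo <- extract_geometry(fld$mask, fld$config$pixel_size)
prof <- extract_profiles(fld$channels, fld$mask, geo)
autoplot(build_demograph(orient_profile(prof), channel = "patch"))
```

## Focus detection

`detect_foci()` band-passes the field with a difference of Gaussians at
(1, 2) × PSF sigma, takes in-mask local maxima above the per-cell
background plus `k_sd = 5` noise SDs (median/MAD estimates, robust to
the foci themselves), merges candidates closer than 2 PSF sigmas keeping
the brighter, and refines each survivor with a Levenberg–Marquardt
isotropic-Gaussian fit in a 7×7 window. Fits are rejected on
non-convergence, non-positive amplitude, or a sigma outside
[0.5, 2] × PSF sigma; accepted centers are assigned to the cell whose
mask contains them. On noiseless spots the fit is exact to well under
0.05 px; at peak SNR 10 the validation suite requires recall and
precision ≥ 0.95 and axial RMSE ≤ 0.5 px against generator truth, with
localization error measured as the axial component of (fitted − true)
center so that pole-pixelation error does not contaminate a detection
metric.

## Extents, colocalization, statistics

`measure_extent()` calls signal intervals on a profile at
`background + alpha × (max − background)` with `alpha = 0.3`, merging
gaps ≤ 2 bins, dropping runs < 3 bins, and interpolating the exact
threshold crossings. No edge-calling rule is published for the nucleoid
measurements this emulates; `alpha` is therefore a documented parameter,
and because absolute fractions depend on it, cross-strain *comparisons*
at fixed `alpha` are the supported use. Polarity classes use a 0.15
polar band and a 0.4–0.6 midcell band, chosen so a 1–2 µm subpolar patch
in a typical 7 µm cell classifies as polar; both are configurable.
`relate_foci_to_nucleoid()` reports each focus's signed distance to the
nearest nucleoid edge in nucleoid lengths (negative = outside).

`pcc_within_mask()` is the plain Pearson coefficient over in-mask
pixels, computed per cell and summarized as mean ± SD over cells —
per-cell ROIs are the biologically meaningful unit, though whole-field
masks can be passed. No Costes randomization or Manders splits are
offered: the quantity mirrored here is plain PCC.

`boxplot_summary()` fixes the quantile estimator to linear interpolation
between order statistics (type 7) with 5th/95th-percentile whiskers.
`mann_whitney()` wraps the rank-sum test: exact null enumeration when
both n ≤ 10 and the data are tie-free, otherwise the normal
approximation with tie and continuity corrections, with the method
recorded; the test suite checks the exact branch against brute-force
permutation enumeration. `compare_strains()` applies both per group
against a designated reference at a default significance level of 0.001,
reports raw p-values, and prints the number of comparisons rather than
correcting — matching the reporting convention it reproduces, while
leaving adjustment to the user.

```{r}
wt <- tibble(strain = "WT", n_foci = 2L, S = 90 + 10 * runif(60))
mut <- tibble(strain = "mut", n_foci = 2L, S = 100 * runif(60))
compare_strains(bind_rows(wt, mut), "S", reference = "WT")$tests
```

## Problem sizes and numerical choices

The validation suite runs entirely on simulated fields: a 50-cell
four-channel field for recovery checks, 200-cell single-channel fields
for detection performance, and two 150-cell populations (symmetric pairs
versus nucleoid-scattered foci) for the end-to-end contrast, all at peak
SNR 10 on 1024²–2048² px fields. These sizes give stable population
medians while keeping a full run in a few minutes; they are package
choices, not statements about the original experiments, whose images are
not publicly deposited and whose headline numbers are therefore not
reproducible from data.

Numerical conventions worth knowing: pixel centers sit at integer
coordinates (0-based lengths measured between extreme pixel-center
projections, so a 100-px rectangle is 99 px long); axial coordinates are
clamped to [0, 1]; all randomness flows through the session RNG, seeded
once per simulation from `sim_config(seed = )`, making truths and
rendered images bit-reproducible; Gaussian spot rendering uses ±5-sigma
windows (truncation < 10⁻⁶ of the mass); the Gaussian-fit acceptance
band and the DoG sigmas scale with the configured PSF sigma rather than
being absolute.

## Known limitations

Straight-axis geometry mismeasures strongly curved cells; the extent
fraction depends on `alpha` near diffuse signals; detection performance
degrades below the validated SNR and separation regime (no claim is made
below ~4 PSF sigmas of separation); and the Mann–Whitney exact branch is
limited to small tie-free groups by design. The segmentation helper
(`segment_simple()`) is deliberately minimal — Otsu plus connected
components — and intended for synthetic or similarly high-contrast
fields; real micrographs should arrive with masks from a dedicated
segmentation tool.
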