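---
title: "Methods: planarity and capture statistics for spheroid microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planarity and capture statistics for spheroid microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroplane)
```

## The problem

Tumor spheroids grown in round-bottom 96-well plates can be transferred en
masse into a molded agar receiver block and embedded for histology. Two
quantities decide whether that workflow is useful:

1. **Capture success** — the fraction of wells whose spheroid actually made
   it into the block, tracked per well, per plate row, and per column
   across replicate plates.
2. **Planarity** — whether the deposited spheroids are coplanar enough that
   a *single* microtome section can cut through all of them. The block is
   imaged by confocal laser scanning microscopy (CLSM) in 30 µm optical
   sections, each spheroid is segmented in 3D, and the scatter of the
   centroids about their best-fit plane is summarized.

`spheroplane` implements both analyses plus a synthetic phantom generator,
so every stage is testable without access to raw CLSM volumes (none were
publicly deposited).

## The planarity statistic

For each segmented spheroid $i$, with surface points $s_{ij}$ and volume
centroid $c_i$:

* mean radius $\bar r_i = \operatorname{mean}_j \lVert s_{ij} - c_i \rVert$
  (physical µm, anisotropic voxel spacing already applied);
* a least-squares plane $z = p_0 + p_x x + p_y y$ is fit to **all**
  centroids of a block by ordinary least squares on the vertical
  residuals;
* $d_i$ is the distance from $c_i$ to that plane, and the reported
  statistic is the dimensionless $d_i/\bar r_i$, summarized by mean,
  median, and max.

$d_i/\bar r_i = 0$ means the plane bisects the spheroid; values above 1
suggest the plane misses it entirely (the package flags those records).
Per-block means are aggregated across blocks as mean ± SD with the $n-1$
standard deviation. We verified the convention on the four published
per-block means: their sample SD is 0.0636 (printed as 0.064), whereas the
population SD would be 0.055 and could not reproduce the printed value.

Two deliberate choices, both configurable:

* **Vertical-residual fit.** The reporting form is $z = p_0 + p_x x + p_y
  y$; only an OLS fit of $z$ on $(x, y)$ yields coefficients in that
  parameterization directly, so that is the default (total least squares
  is not offered — it estimates a different object).
* **Perpendicular distance.** The published description says only
  "distance to the plane". At the slope magnitudes observed in real
  blocks ($|p| \le 0.017$) the perpendicular and vertical readings differ
  by under 0.02%, so the distinction is immaterial there, but
  perpendicular is the geometrically standard reading and is the default;
  `distance_mode = "vertical"` switches it.

Even-sized medians are the mean of the two central order statistics
(`stats::median`).

## The synthetic world

`scene_config()` + `generate_block_scene()` draw one realization of a
stated world and `render_stack()` voxelizes it. The defaults *are* the
published experimental conditions wherever those are stated:

| parameter | default | provenance |
|---|---|---|
| grid | 8 × 12 | 96-well plate |
| `pitch` | 3800 µm | funnel-outlet spacing of the device |
| `mean_diameter` | 500 µm | reported average spheroid diameter |
| `capture_prob` | 0.8 | reported 80 ± 11% transfer success |
| `section_thickness` | 30 µm | reported optical section thickness |
| field | 25 × 15 × 1 mm | reported scan region |
| `voxel_xy` | 10 µm | chosen: resolves a 500 µm spheroid with ~50 voxels across |

Values the source experiments do not pin down were chosen once, on realism grounds, and
are not tuned:

* `diameter_cv = 0.1`, `axis_ratio_range = c(0.8, 1.2)`: spheroids are
  described qualitatively as non-spherical ("more of an ellipsoid");
  ±20% axis ratios with volume-preserving normalization and uniformly
  random orientation reproduce that without inventing shape statistics.
* `z_noise_sd = 60` µm: gives an expected mean normalized distance
  $\sigma\sqrt{2/\pi}/\bar r \approx 0.19$, the scale of the reported
  0.27 (which also absorbs bowing and real segmentation error), while
  keeping 500 µm spheroids inside the 1 mm imaging depth.
* parabolic bowing (`bowl_coeff`, 1/µm) acts along $x$ only, matching the
  reported depression running parallel to the y-axis; it is off by
  default.
* depth attenuation is exponential in the tissue path length between a
  voxel and the objective (+z side), with configurable
  `attenuation_length` (the dimming is reported only
  qualitatively). The deepest occupied section of a spheroid is therefore
  the dimmest.

All randomness flows from one integer seed; plates and the rendering noise
use deterministic 31-bit sub-streams, so any artifact is reproducible from
`(config, seed)` alone.

### A geometry conflict, resolved in favour of the scan region

The stated funnel pitch (3800 µm) times 12 columns spans 41.8 mm — wider
than both the stated 2.5 cm scan region and a histology cassette interior.
The two statements cannot both describe the deposited array. The package
keeps 3800 µm as the `scene_config()` default (it is the stated device
value and valid for scenes that are never rendered), while rendered
demo and test scenes use scan-region-compatible pitches (e.g. 2000 × 1800
µm) so that a full 8 × 12 array fits the imaged field. Similarly, the
published plane heights (p0 up to 888 µm) place 250 µm-radius spheroids
above a literal 1 mm depth, so plane-recovery phantoms use a 1.4 mm
imaging depth — the published numbers themselves imply the "approximately
1 mm" scan was nominal.

## Segmentation choices

* **Global Otsu threshold** by default: the whole-cell stain yields a
  strongly bimodal histogram. The histogram is accumulated in chunks so
  gigavoxel volumes do not allocate gigabyte temporaries. A fixed
  threshold is available. An all-foreground result raises a warning and
  is flagged in the result metadata rather than erroring.
* **26-connectivity** for component labelling (C++ BFS), **6-connectivity**
  for the surface definition — the tighter boundary, matching the
  brute-force enumeration oracle exactly on digital balls.
* **Unweighted volume centroid**, not intensity-weighted: depth-dependent
  attenuation would bias an intensity-weighted centroid toward the
  objective.
* `min_volume` defaults to the volume of a 150 µm sphere (debris filter);
  well assignment takes the nearest grid node within `pitch/2`, one
  spheroid per well, nearest wins, losers reported unassigned.

At the default resolution (10 µm xy, 30 µm z) the recovered $\bar r$ of a
rendered 500 µm sphere is biased low by a few percent (surface voxels sit
half a voxel inside the analytic surface, and the coarse z-sampling clips
the caps); the test suite pins this at under 10%. The normalized statistic
divides out most of the effect.

## Capture statistics

Per-well success is the elementwise mean of the boolean plate maps. Row
and column effects are tested with a two-sided one-sample t-test against
the grand mean success rate computed from the same data, at α = 0.01 with
a *strict* p < α rule. The sample unit is the **per-plate row (column)
mean** (n = number of plates): plates are the independent replicates, and
row effects plausibly arise from per-plate handling. The published analysis does not
state its sample unit; `unit = "well"` provides the alternative. No
multiple-testing correction is applied by default, matching the original
presentation; `bonferroni = TRUE` is available. Zero within-sample
variance is reported as p = 1 (mean equals null) or p = 0 with an
infinite-t flag (mean differs) rather than NaN.

Because the null value is estimated from the same data, the row test is
slightly conservative-to-liberal depending on configuration; simulation in
the test suite bounds the empirical type-I rate at α = 0.01 below 0.05.

## Trend surface

`loess_surface()` fits a locally weighted regression of centroid $z$ on
$(x, y)$ — tricube weights, `span = 0.5`, local degree 2, no robustness
iterations, exact ("direct") surface evaluation. Degree 2 is the smallest
local model that can follow the parabolic depression seen in deformed
blocks. $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ is computed at the observed
centroids; constant-z input flags $R^2$ as undefined instead of dividing
by zero. The published trend $R^2$ of 0.87 depends on the original data
and the original (unstated) smoothing parameters, so it is matched in
definition, not in value.

## What a green test establishes — and what it does not

The phantoms exercise geometry, sampling, attenuation, Bernoulli capture,
and Gaussian centroid scatter. They do **not** simulate a point-spread
function, photobleaching, touching spheroids (the array pitch keeps
objects separated by construction), debris other than sub-`min_volume`
specks, or non-Gaussian deformation of the agar block. Passing tests
establish that the estimators recover their own stated world (plane
coefficients to 1e-6 relative at centroid level, p0 to ~0.01 µm through
the full voxel pipeline, half-normal calibration of the normalized
distance, ≥90% power for a 0.8→0.4 row suppression at six plates) — they
cannot certify performance on real CLSM volumes with optical artifacts.

## Numerical and format notes

* Volumes are (z, y, x) arrays with physical spacing (dz, dy, dx) in µm;
  voxel *i* is centred at $(i-0.5)\cdot\text{spacing} + \text{origin}$;
  z increases away from the block bottom; A1 is the origin corner.
* Stacks interchange as uncompressed baseline multi-page TIFF (8/16-bit
  unsigned, or 32-bit float for un-rescaled synthetic intensities); the
  reader refuses compressed, multi-sample, or unequal-page files rather
  than guessing. No R TIFF package was available in the target
  environment, so the small required subset is implemented directly and
  cross-validated against Python's `tifffile`.
* Configs serialize as JSON (no YAML parser in the target environment);
  `Inf` round-trips as the string `"Inf"` and `NULL` as `{}` — the reader
  normalizes both.
* Plane fits use a QR decomposition and reject rank-deficient (collinear
  xy) configurations explicitly.
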