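---
title: "Single-cell mechanophenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell mechanophenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
library(dplyr)
```

`cellmech` quantifies the mechanical phenotype of primary B lymphocytes from
four complementary single-cell readouts — AFM force spectroscopy, hypoosmotic
swelling, super-resolution actomyosin morphometry, and real-time
deformability cytometry (RT-DC) — and compares cohorts (e.g. healthy donor B
cells versus chronic lymphocytic leukemia cells, strata such as IGHV status
or BTK-inhibitor treatment) with Mann-Whitney tests. Because patient material
cannot ship with a package, every stage is paired with a seeded synthetic
generator that emits raw data *plus a ground-truth table*, so the pipeline is
validated by parameter recovery rather than by frozen example outputs.

## Cortical stiffness from AFM force spectroscopy

A soft cantilever (nominal spring constant 0.1 N/m) indents the cell over a
4 µm ramp up to about 1 nN. The recorded approach curve is piezo position
`z` versus force `F`. Analysis proceeds in four steps, all exposed as
functions:

1. **Baseline correction** (`baseline_correct()`): a line fitted to the
   far-field half of the ramp removes photodiode offset and drift tilt.
2. **Contact point** (`find_contact_point()`): the curve is modelled
   piecewise — zero force before contact at `z0`, the Hertz-Sneddon law
   beyond. Every sample in the central 80% of the ramp is tried as a
   candidate `z0`; the modulus is profiled out by linear least squares at
   each candidate (the model is linear in `E` once `z0` is fixed), and the
   best grid point is polished by 1-D optimisation. A curve whose best
   piecewise fit fails to improve on the flat no-contact model by at least
   5% is flagged invalid. We chose the joint piecewise fit over threshold
   crossing because it remains usable at a few pN of noise and can be
   checked against exhaustive search.
3. **Bending correction** (`to_indentation()`): indentation is
   `delta = (z - z0) - F/k`; the `F/k` term removes the cantilever's own
   deflection.
4. **Modulus fit** (`fit_hertz_sneddon()`): for the default four-sided
   pyramidal probe, `F = (tan theta / sqrt(2)) * E/(1 - nu^2) * delta^2`.
   Conical and spherical indenters are also provided. The fit uses only
   `delta <= 500 nm` — the shallow regime probing the actin-rich cortex
   rather than the bulk — and reports `r^2` and a validity flag
   (`r^2 >= 0.9` and `E` within 10–1e5 Pa by default; both configurable,
   since per-curve QC rules are lab conventions rather than physics).

Parameter choices worth stating: the Poisson ratio defaults to the
incompressible limit `nu = 0.5` (so `1 - nu^2 = 0.75`), standard for living
cells; the face half-angle defaults to 17.5°, the nominal geometry of the
soft pyramidal levers used for lymphocytes. Both are arguments of
`tip_geometry()`. Because the same forward model drives the generator and
the fit, recovery tests are insensitive to the particular prefactor
convention; what they do verify is baseline handling, contact detection,
bending correction and the capped least-squares machinery.

Units are nm and pN internally (so `F/k` converts as
`pN * 1e-3 / (N/m) = nm`), with Pa at the interface; all conversions live in
one place.

Per cell, the standard protocol records a 4 × 4 grid over 1 × 1 µm²;
`afm_summarize_cells()` reduces the valid per-curve moduli to their median
(robust against contact failures) and requires at least 4 valid curves,
otherwise the cell is flagged undefined.

## Hypoosmotic swelling kinetics

Adhered cells are imaged in bright field at 1 frame/s for 30 min; water
injection after the first 50 s drops the osmolarity and the cells swell.
Per frame, `segment_frame()` inverts the image (cells are dark), smooths
with a 2 px Gaussian, extracts H-maxima markers (maxima deeper than `h`,
default 10% of the dynamic range — the transform is named by the protocol
but its depth is not, so it is exposed as a parameter) and grows regions
from the markers over the foreground by intensity-guided propagation, i.e.
marker-controlled watershed. The grayscale reconstruction behind the
H-maxima transform is computed by iterated masked dilation; markers are
searched on a 2× down-sampled copy of the smoothed frame — a pure cost
optimisation, since region boundaries are always drawn at full resolution.
The cell radius is half the moment-equivalent major axis of the region,
matching the protocol's radius definition and making the estimator exact
for both circular and elliptical cells.

Tracking (`link_tracks()`) is greedy nearest-centroid linking with a 10 px
jump cap and a 2-frame gap cap (bridged by interpolation): adhered cells
barely move, so anything more elaborate would be unidentifiable from the
data. Gaps and cap defaults are arguments.

Kinetics follow `R(t) = R_in + (R_fin - R_in) * (1 - exp(-(t - t0)/tau))`
for `t >= t0`. In `fit_swelling()`, `R_in` is fixed to the pre-injection
mean radius rather than fitted: it is measured directly by the first 50 s
of frames, and freeing it correlates strongly with `R_fin` on noisy tracks.
`tau` starts at 100 s. Constant-radius tracks return ratio 1 with `tau`
flagged unidentifiable rather than an arbitrary number. The pooled
("global") fit normalizes each track by its own `R_in` and fits a shared
`(ratio, tau)` on the pooled cloud; normalizing first keeps cells of
different sizes exchangeable, and whether the original analysis pooled raw
or normalized radii is not documented — this package defines it as
normalized, and the per-cell route is always available for comparison.
The headline statistic is the swelling ratio `R_fin / R_in`.

## Actomyosin morphometry and colocalization (STED-scale)

Single optical sections (top, equatorial, bottom) are analysed
independently in 2-D. Three metrics:

* **Meshwork density** (`density_percent()`): the percentage of the ROI's
  total fluorescence intensity that falls on structure pixels. The
  alternative reading — above-threshold *area* fraction — is exposed as
  `mode = "area"`, but intensity fraction is the default interpretation of
  "intensity counts over the ROI total area intensity".
* **Filament morphometry** (`skeletonize_and_measure()`): the structure
  mask is thinned to a 1-px skeleton with the Guo-Hall algorithm. We use
  Guo-Hall rather than the more common Zhang-Suen because Zhang-Suen
  reduces oblique strokes to a two-pixel staircase whose tip keeps
  satisfying the deletion rule and the line "unzips" from its ends,
  shortening diagonal filaments by tens of pixels; Guo-Hall's connectivity
  test protects those tips. The skeleton is converted to a pixel graph in
  which diagonal links that parallel an axial two-step path are dropped, so
  vertex degrees reflect true line topology; spur branches up to 3 px
  (below the resolution scale) are pruned. Filament length is measured by
  walking each junction-free chain and summing a polygonal path resampled
  every 4 px — raw 8-connected step counting overestimates length by up to
  8% depending on orientation — and each loose end is extended by its
  distance-transform value minus half a pixel, compensating the cap
  retraction intrinsic to thinning. Branch points are skeleton pixels of
  degree ≥ 3, with adjacent branch pixels merged into one junction cluster
  so a thick crossing counts once. Filaments are retained only if strictly
  longer than 260 nm (the experimental resolution cutoff); shorter ones are
  kept in the table but flagged and excluded from the per-cell summaries
  (median filament length, mean branches per filament).
* **Manders colocalization** (`manders_percent()`): the default is the
  intensity-weighted coefficient — the percentage of the assessed channel's
  total ROI intensity lying where the reference channel is above threshold.
  A pixel-count mode (`|A-mask ∩ B-mask| / |A-mask|`) is also exposed, as
  the phrase "colocalized actin pixels" is ambiguous between the two; both
  agree in the degenerate identical/disjoint cases the tests pin down.
  Thresholds default to per-image Otsu, with fixed values recommended for
  batches acquired under identical conditions.

## RT-DC shape descriptors

Events arrive as closed contour polygons (≥ 8 vertices) with an optional
pixel mask. Area is the shoelace formula, perimeter the vertex arc length,
and deformation the circularity deficit `D = 1 - 2*sqrt(pi*A)/P` — the
descriptor of the RT-DC analysis software this pipeline mirrors; the
original study prints no formula, so this definition is adopted from the
methodology it cites. The polygon perimeter (not the pixel-boundary crack
length) defines `P`, matching the contour-based definition. The area ratio
(pixel-mask area over polygon area) gates events whose contour misses the
cell periphery: `area_ratio <= 1.05`, boundary inclusive. Per experiment,
the summary is the median deformation and mean cross-sectional area over
kept events. Young's-modulus inversion from deformation (an external
finite-element model in the original workflow) is out of scope; channel
and flow metadata are carried but not modelled.

## Cohort statistics

`mann_whitney_u()` wraps the two-sided rank-sum test: exact null
distribution when `n1*n2 <= 400` with no ties, otherwise the normal
approximation with tie and continuity corrections. Stars follow the
reporting thresholds 0.05 (*), 0.005 (**), 0.0005 (***), strict
inequalities. `stratify_and_compare()` runs all pairwise group comparisons
within strata (IGHV status, treatment, compartment) and reports unadjusted
p values by default, matching the original reporting; Bonferroni is an
option. Cell-level pooling across donors mirrors the scatter plots of the
source workflow; per-experiment medians (RT-DC) use
`summarize_experiment()`.

## What the generators emulate — and what they do not

Each generator draws from one integer seed and emits a truth table
(id, stage, parameter, value, units):

* `sim_force_curves()` produces exact forward-model curves including the
  cantilever-bending feedback (the recorded force solves
  `F = C E ((z - z0) - F/k)^2`, which has a closed-form root), flat
  pre-contact baselines and Gaussian force noise.
* `sim_swelling_stack()` renders dark disks with a 2 px sigmoid edge,
  1 px Gaussian blur and configurable SNR at 200 nm/px; radii follow the
  exponential law exactly. Overlapping final-size specifications are
  rejected.
* `sim_filament_image()` rasterizes polylines at 20 nm/px, blurs with a
  Gaussian PSF (default FWHM 60 nm; generation refuses undersampled
  pixel/PSF combinations) and applies Poisson shot noise plus Gaussian
  read noise — photon-counting realism at desk cost.
* `sim_coloc_pair()` splits the assessed channel's intensity between the
  inside and outside of the reference structure so the colocalized
  fraction is exact by construction.
* `sim_rtdc_events()` solves the ellipse aspect ratio against the
  *polygon* descriptor, so the generated contour's deformation equals the
  target exactly rather than up to a discretization offset; "rough" events
  receive boundary spikes in the mask (not the contour) until the area
  ratio exceeds the gate with margin.

None of this emulates real optics: no aberrations, no depth structure, no
deconvolution artifacts, no detector-specific noise, no cell-to-cell
contact or debris. Passing recovery tests therefore demonstrates that the
analysis is correct and well-conditioned under controlled conditions — not
that it is robust to every failure mode of real microscopy data. The
parameter values used as simulation targets (stiffness medians 785.1 and
484.0 Pa; swelling ratios 1.39 and 1.68; deformation medians 0.034 and
0.029; mean sizes 35.0 and 33.6 µm²; Manders medians 34.0% and 18.2%) are
cohort summaries of the study this pipeline re-implements, used here as
known ground truth for recovery.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts scaled for a single
core: 10-20 cells per swelling cohort at 0.08-0.1 Hz sampling over ~20 min
of simulated time, 200 noisy force curves, 20-filament meshworks,
5000-10000 RT-DC events, 1000-replicate null calibrations. These sizes were
chosen so each stage's recovery error is dominated by the method, not by
sampling noise.

Degenerate inputs are defined rather than accidental: blank frames
segment to zero regions; a single-pixel region has radius half a pixel;
constant-radius tracks are unidentifiable, not an error; empty filament
masks yield empty graphs; a missing RT-DC mask means area ratio 1 with a
flag; uniform images refuse Otsu thresholding with a pointer to fixed
thresholds; ties switch the Mann-Whitney test to the corrected
approximation with a warning in forced-exact mode.

## Known limitations

* Contact-point localisation degrades for very soft cells (< 100 Pa) where
  the force emerges from the noise floor deep into the ramp.
* The tracker assumes near-stationary cells; it is not a general-purpose
  multi-object tracker.
* Filament end-correction is calibrated for isolated strokes; dense
  meshworks whose filaments overlap within a PSF width will merge into one
  component and are reported as such.
* The RT-DC module analyses supplied contours; it does not extract
  contours from video, and it does not invert deformation to elasticity.
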