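---
title: "Measuring single-nephron GFR from dye-front imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-nephron GFR from dye-front imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sngfr)
```

## The measurement model

Single-nephron glomerular filtration rate (snGFR) is the volume of primary
filtrate one nephron produces per unit time. After a bolus of a freely
filtered, non-resorbable fluorescent dye, the proximal tubule (PT) fills at
exactly that rate: the dye front's position along the tubule, expressed as
*swept tubule volume*, grows linearly in time with slope equal to the
filtration flow. Everything this package does serves that one identity,

$$ V(t) = V_0 + Q\,t, \qquad \widehat{snGFR} = \hat\beta_1 \cdot
   \mathrm{fps} \cdot 60 \cdot 10^{-6} \;\text{nl/min}, $$

where $\hat\beta_1$ is the ordinary-least-squares slope of front volume
(µm³) on frame index and $1\,\mathrm{nl} = 10^6\,\mathrm{µm^3}$.

The measurement decomposes into two independent calibrations:

1. **Where is the front?** A kymograph $I(s, t)$ samples the dye intensity
   along a hand-drawn polyline ROI (arclength $s$) in every frame $t$, by
   bilinear interpolation on a regular grid (default spacing: one pixel —
   no super-resolution pretense; default line width 1 px). The front in a
   frame is the end of the initial contiguous above-threshold run scanned
   from the glomerular end, refined by linear interpolation between the
   bracketing samples. Scanning from the upstream end makes the localizer
   robust to dye re-entering the field further downstream.

2. **How much tubule lies behind it?** The tubule is modelled in 3D from a
   co-registered z-stack: 3D median filter, bleed-through subtraction,
   Otsu binarization, distance-transform-seeded 3D watershed, and selection
   of the basins whose x-y projection meets the dilated ROI. Each mask
   voxel is assigned the arclength of the orthogonal projection of its
   (x, y) centre onto the ROI (z is ignored: the time series is a single
   plane, and the projection in the drawn plane is the only correspondence
   the ROI defines). The cumulative count times the voxel volume gives the
   monotone map $V(s)$ that converts front positions to front volumes.
   Voxels projecting beyond either end of the polyline are excluded and
   counted in the run log. Ties between segments resolve to the smaller
   arclength, which keeps the map direction-stable.

## The adaptive threshold

At a fixed position, dye arrival is sigmoidal: baseline, rise as the front
passes, plateau. The rise's turning point (maximum slope over time) sits at
half-maximum for a logistic curve, which makes it a natural,
intensity-scale-free definition of "the front is here now". Per retained
position the package takes the frame of maximal forward difference of the
(optionally smoothed) arrival curve and records the mean of the two
intensities flanking that step; the global threshold is the **median** of
these per-position turning intensities. A single global threshold (rather
than per-position thresholds) matches how the front is then located — one
dashed line across all curves — and the median makes it robust to positions
the dye never reaches or that are corrupted by noise. Positions whose total
intensity rise is below 25% of the largest rise anywhere are considered
untouched by the dye and excluded from the vote.

The turning point is deliberately estimated by a discrete forward
difference, not by fitting a sigmoid: the estimator then assumes nothing
about the rise shape. The cost is frame-level quantization, which the
centred moving-average pre-smoothing (default window 3 frames, odd,
truncated at the edges) keeps in check. Because the whole chain —
difference, argmax, flanking mean, median — is homogeneous of degree one in
intensity, multiplying the data by any constant scales the threshold by the
same constant and leaves the front trace and the snGFR untouched.

## Frame trimming and the regression

Frames where the front has not yet entered the ROI, or has already left it,
carry no slope information but would bias least squares (flat plateaus at
0 or $V_{total}$). The tracker therefore drops frames whose front volume
falls outside (5%, 95%) of the total tubule volume, and requires at least
three surviving frames. The regression runs on frame index and converts to
physical units afterwards — numerically identical to regressing on seconds,
but mirroring how the data are recorded (µm³ per frame). R² is the squared
Pearson correlation of the surviving (frame, volume) points; it is reported
`NA` when the front never moves, rather than a spurious score.

## The two-point comparator

The previously published method is retained as an honest comparator:
intensity curves at the ROI's first and last vertices, arrival at each
point by the same maximum-slope estimator, and the tubule volume as a
cylinder over the mean of five manual diameters. Using one arrival
estimator for both workflows isolates their structural difference — two
points plus an assumed cylinder versus continuous measurement plus a
segmented 3D volume — which is exactly what the repeatability comparison is
about. Because each arrival is quantized to a frame, the transit time is
accurate to about one frame; with only two measurement points there is no
averaging to absorb that error, which is one of the two reasons the
two-point replicate spread is larger (the other being the manual
diameters, whose error enters squared).

## Acquisition metadata

Three numbers link pixels to physics: lateral pixel size (µm), z spacing
(µm), frame rate (fps). They are deliberately read from a sidecar config
(YAML/JSON), not from TIFF tags, which exporters fill inconsistently; and
the pipeline refuses to run without them — a wrong pixel size corrupts
snGFR cubically and silently. The package's reference defaults (0.8513 µm,
1 µm, 6 fps) describe the multiphoton protocol the workflows were developed
around (40×/1.1 NA water immersion).

## The phantom: what it emulates, what it does not

The generator renders the *signal model the analysis assumes*: a tube of
known geometry (straight, sine or arc centreline; constant or linearly
tapering radius) whose dye occupancy advances along arclength as
$s(t) = V^{-1}(Q t)$, with a ~1-pixel soft edge both radially and at the
front, Gaussian noise as a fraction of the intensity plateau, a parallel
vessel and scattered nuclei as companion-channel structures, and a
configurable fraction of those structures bled into the dye channel. The
rendered front keeps advancing past the field of view, so the most distal
ROI position brightens at the physically correct time (in vivo, the dye
flows on into unseen downstream segments). All intensities are rounded to
integers so that written TIFFs round-trip bit-exactly, and every random
draw derives from the phantom's seed.

Default geometry: a 64×64×20 voxel stack at 3 µm lateral pixels and 2.5 µm
sections (~192×192×50 µm — a downsampled field of view), lumen radius
15 µm, flow 1.7 nl/min at 6 fps over 30 frames, noise 5%. These values were
fixed jointly so that (i) a physiological flow produces a front transit
spanning most of the series — at 1.7 nl/min ≈ 4722 µm³/frame and
π·15² ≈ 707 µm² of lumen cross-section the front moves ≈ 6.7 µm/frame and
crosses the 171 µm tube in ≈ 26 frames; and (ii) the radius spans at least
5 voxels per axis, keeping the voxelized volume within 5% of π r² L. At the
native 0.8513 µm pixel of the reference protocol, a 64-pixel field is only
54 µm wide and no lumen that fits it could carry 1.7 nl/min at an
observable front speed, so the phantom's calibration represents a coarser
sampling of the same physical scene.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data: out-of-focus light and depth-dependent attenuation,
photobleaching, breathing/peristaltic motion, tubule curvature out of the
imaging plane, partial dye reabsorption or secretion, and the glomerulus
itself. The phantom validates the *computational* chain (segmentation,
volume mapping, thresholding, regression), not the biological imaging
conditions.

## Numerical choices and degenerate inputs

* **Otsu threshold**: between-class variance maximized over a 256-bin
  histogram of the data range; a tied plateau of equally good splits (empty
  bins between well-separated modes) resolves to the plateau centre, so the
  threshold falls midway between the modes. Constant volumes are an error.
* **Watershed**: seeds are local maxima of the anisotropic Euclidean
  distance transform (voxel dimensions in µm), greedily thinned to a
  minimum separation of 5 voxels; flooding follows decreasing distance with
  FIFO tie-breaking, so results are deterministic. Every foreground voxel
  receives exactly one label. The ROI then selects the union — not the
  argmax — of intersecting basins, because a long tubule may legitimately
  split into several basins.
* **Cumulative volume**: a staircase in arclength with bins of one grid
  spacing; its discretization error is bounded by the surface-voxel layer
  of the truncated tubule. Constant offsets in $V(s)$ do not affect the
  regression slope.
* **Front localization**: returns "no front" for profiles that start below
  threshold or never drop below it; both cases are dropped by the tracker,
  and fewer than three usable frames abort the analysis with a clear error
  rather than a meaningless fit.
* **Time-reversed (or refluxing) data** produce either that error or a
  negative slope — never a silently positive snGFR.
* **Median filter** uses edge replication, preserving constants exactly;
  radius 0 is the identity. Bleed-through subtraction clamps at zero,
  matching unsigned-integer image arithmetic.

## The repeatability statistics

Per dataset (one glomerulus, analysed repeatedly): mean, sample SD (n−1)
and relative SD `100·sd/mean` (%). Per workflow: the unweighted mean of the
per-dataset relative SDs ("mean CV"), and mean ± sample SD of the
per-dataset means. These conventions reproduce the bundled published
summary table's aggregate figures (mean CV 10.35% extended vs 38.75%
previous; extended mean snGFR 1.70 ± 0.78 nl/min), which is how the
conventions were confirmed. One caveat a user should know: the
previous-workflow per-dataset means in that table average to 1.716
(rounding to 1.72), while the published aggregate rounds to 1.71 — the
difference is consistent with the aggregate having been computed on
unrounded replicates. The two-sample Kolmogorov–Smirnov comparison uses the
exact small-sample p-value when $n\,m < 10^4$ and the samples are tie-free,
and reports which method was used.

The `jitter_study()` harness is the computational analogue of repeated
manual analysis: per replicate it perturbs the ROI vertices with Gaussian
jitter (default SD 1 px, re-tracing error) and the manual diameters with
multiplicative noise (default CV 10%, a realistic manual re-measurement
error), then runs both estimators on the same rendered phantom. On the
default phantom the extended workflow's replicate CV is well below 1% while
the two-point workflow's is near 10% — the same ordering, for the same
structural reasons, as in repeated analysis of real data.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 64×64×20
stacks with 30 frames, 20 replicates for the noise study and 20 for the
jitter study; a single end-to-end run takes well under a second, the whole
acceptance script under a minute. These sizes were chosen as the smallest
geometry that keeps the lumen at ≥ 5 voxels radius; estimator behaviour is
scale-free beyond voxelization.

## Known limitations

* The ROI is authoritative: the package never re-estimates the tubule
  centreline from the segmentation, so a badly drawn ROI biases both
  workflows (by design — the same is true at the microscope).
* The volume map ignores z when assigning voxels to arclength; tubules
  that loop over themselves in the x-y projection would be mis-assigned.
* One global threshold assumes the dye plateau is comparable along the
  tubule; strong depth-dependent attenuation would argue for per-position
  thresholds, at the cost of noise sensitivity.
* R² is the only fit diagnostic reported; no confidence interval is placed
  on snGFR itself.
* The `.lif` container is not read; export to TIFF (e.g. via Bio-Formats)
  first.
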