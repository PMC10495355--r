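---
title: "Quantifying multiscale predatory motility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiscale predatory motility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxotrack)
```

## The problem

*Myxococcus xanthus* preys on *Escherichia coli* by invading the prey lawn as
a structured community: isolated, fast-moving **scouts** explore ahead of the
invasion front, **loners** sit near the colony edge, and densely packed
**swarms** move collectively, often retracing the paths scouts laid down.
Time-lapse microscopy of such predation assays produces, after semantic
segmentation, per-frame integer label masks for the predator cells and a
fluorescence channel for the prey. `myxotrack` turns those stacks into
single-cell trajectories, per-cell spatial context, behavioural classes,
kinematic statistics, class-transition kinetics, trail-overlap measures and
prey-consumption curves — together with a synthetic scene simulator that
generates the same data with full ground truth, so every stage can be
validated by parameter recovery.

## Tracking model

Masks in consecutive frames are linked by a composite similarity score over
three bounded criteria: mask overlap (overlap area divided by the smaller
mask area), area ratio (min/max) and backbone-length ratio (min/max). The
criteria are combined by weights obtained as the normalized principal
eigenvector of a pairwise-comparison matrix, following the Analytic Hierarchy
Process; the default matrix encodes overlap ≻ area ≻ length with ratios 2:1
and 3:1 (consistency ratio < 0.1) because pixel overlap is the most reliable
cue in dense regions, but the matrix is a plain argument and can be replaced.
Candidates are restricted to pairs within a 30 px search radius (about one
cell length at the default morphology) or with nonzero overlap, and the
frame-pair assignment is the maximum-weight bipartite matching over
candidates scoring at least `min_score` (default 0.1) — solved exactly, and
verified in the tests against brute-force enumeration on small instances.
Masks whose pixels overlap two or more predecessors are flagged as fusions
and terminate the incoming tracks rather than merging them; gap closing
across missing frames is deliberately not attempted.

## Spatial context

Local density uses a Voronoi tessellation seeded at the midpoints of mask
backbones. Backbones are topological skeletons (Zhang–Suen thinning); a
skeleton pixel with crossing number ≥ 3 is a branchpoint and is deleted,
splitting the backbone into segments whose midpoints all seed the
tessellation (a mask's own polygon is the one of its longest segment).
Polygons are clipped to the field rectangle, so every area is finite and the
areas sum exactly to the field area; the per-seed areas are verified against
a nearest-seed pixel-count oracle. The inverse polygon area is the local
density, and `log10(V)` of the polygon area (px²) is the classification
coordinate.

Long-range clusters come from dilating the binary mask union with a square
10 × 10 px structuring element (≈ 1 × 1 µm at 106 nm/px) and taking connected
components. Because an even kernel has no exact centre, the element is
anchored at the top-left pixel of its central 2 × 2 block — a convention the
tests pin down against an explicit pixel-set dilation oracle. The cluster
size `N` is the summed *non-dilated* member area divided by the mean
single-cell area; by default that mean is the median area of masks forming
single-mask clusters in the frame, a choice that is robust to fused masks
(how the mean single-cell area is estimated is genuinely open; it is
configurable). `N` is generally non-integer.

Masks whose backbone tortuosity (arc length over end-to-end distance) exceeds
1.5 are flagged: they still seed the tessellation but are meant to be
excluded from kinematic statistics, since high tortuosity usually indicates a
segmentation fusion.

## Classification

The decision rule on `(log10(V), N)` is:

| class | rule |
|---|---|
| scout | `log10(V) ≥ 4.5` and `N ≤ 20` |
| loner | `log10(V) ≤ 4.5` and `N ≤ 2` |
| swarm | `log10(V) ≤ 4.5` and `N > 2` |

On the shared boundary `log10(V) = 4.5` the scout rule takes precedence
(isolation is the marked condition). The region `log10(V) > 4.5, N > 20` is
covered by no rule; rather than inventing biology we return `"unclassified"`.
The boundaries are recoverable from the classifier itself by sweeps and
bisection, which is exactly what the acceptance checks do.

The motile filter keeps tracks whose end-to-end displacement strictly
exceeds 2 px. A variant normalizing the displacement by track duration is
available by flag, because both formulations appear in the field; the
absolute form is the default.

## Kinematics

* **Instantaneous speed** at frame *t* is the straight distance between the
  positions five frames before and after *t*, divided by the time spanned by
  the ten frames; endpoints without a full window are skipped, never
  zero-filled.
* **Gyration radius** is the *mean* (not RMS) distance of trajectory points
  from the trajectory centroid.
* **Directionality** is the slope α of an ordinary least-squares fit of
  `log MSD` against `log lag` over the first five lags, with the MSD computed
  as a time average over all overlapping start points (cross-checked against
  a double-loop oracle). α < 1 indicates confined, α = 1 Brownian and α > 1
  directed motion; a zero MSD among the fitted lags makes the fit
  ill-defined and is reported as missing.

## Transitions

Per-frame class series are smoothed with a 10-frame rolling mode (centred,
truncated at the ends — padding would invent labels; for the even window the
centre covers offsets −5…+4). Modal ties break by the fixed priority
scout < loner < swarm purely for determinism. A transition event is any
frame-to-frame label change; probabilities are row-normalized over change
events (self-transitions excluded), with a dwell-including per-frame variant
by flag since both conventions are defensible. The triangle embedding maps
each frame to the corner of a unit-side equilateral triangle (scout, loner,
swarm counterclockwise) plus isotropic Gaussian jitter, default sd 0.05 side
lengths — the geometry and jitter are fixed here for reproducibility.

## Trails

Trajectories are rasterized as 8-connected discrete segments onto a grid,
each touched pixel aggregating the mean visit time. Tracks are partitioned
framewise by class (a cell contributes each segment to the map of the class
it holds when traversing it), giving a scout map and a rest-of-population
map. The two maps are binarized and compared by a per-pixel structural
similarity index over a 3 px sliding window with the standard stabilizing
constants `C1 = (0.01 L)²`, `C2 = (0.03 L)²`, `L = 1`; borders are reflected.
The SI map is binarized (default threshold 0.5) and its connected
components are the shared-trail segments, reported by pixel area. Two
identical empty windows also have SI = 1, so shared-segment extraction is by
default restricted to pixels occupied in both maps. For full-scale data the
trail grid is 5880 × 5880; synthetic scenes use a grid equal to the field
size, scaled down proportionally.

## Prey consumption

The prey channel is divided pixel-wise by the Gaussian excitation profile
(supplied, or fitted to the temporal median image by log-linear regression —
an exact fit for a noiseless Gaussian over an intact lawn, and only intended
for mostly-intact lawns). The field is split into three equal bands along
the invasion axis: predation zone (invaded end), unused middle, and safe
zone; per-band mean intensities are normalized to their first frame. The
predation series is divided by the safe series — both carry the same
photobleaching factor `exp(-bt)`, so the ratio removes it identically — and
a single exponential is fitted: a log-linear fit on the above-noise head of
the series initializes a linear-scale least-squares refinement, which is
robust to the noisy near-zero tail. "Decay time" is the fitted time constant
τ; the literature does not pin this estimator down, so a half-life variant
(first crossing of 0.5) is available by flag. Non-decaying series are
flagged rather than given a spurious τ.

## The synthetic scene generator

`simulate_scene()` emulates the statistical structure the pipeline assumes:

* rod-shaped cells rendered as axis-capsules (rectangle plus semicircular
  caps) at configurable length/width — default 40 × 6 px ≈ 4.2 × 0.6 µm at
  the default 106 nm/px — over hundreds of frames at a default 38 s interval
  (midpoint of a 35–40 s acquisition cadence);
* three motion modes: directed (persistent heading, default 2 px/frame with
  0.1 rad/frame heading noise, a realistic gliding speed of ≈ 0.3 µm/min),
  Brownian (1 px/frame step sd) and confined (reflecting disk);
* cohesive swarm groups whose members jitter about a moving group centroid,
  clamped within a 30 px cohesion radius, plus isolated scouts and loners;
* per-cell Markov class series at configured per-frame rates (default 0.02
  to each other class — the underlying study reports no numerical rates, so
  this is a free parameter chosen to give several transitions per
  400-frame track) with ground-truth transition events;
* a trail-following knob: that fraction of each swarm group's members
  retraces a scout's path with a per-member lag (the k-th follower lags
  `60/k` frames), so the shared-trail area grows strictly with the knob;
* a prey lawn decaying exponentially behind an advancing front (defaults:
  0.05/frame lysis, 2 px/frame front), rendered through a centred Gaussian
  excitation profile with exponential photobleaching (0.002/frame) and
  additive Gaussian noise, clipped at zero.

Overlapping cells are resolved by z-order (the later id wins contested
pixels) because label images are single-valued; the ground truth keeps every
cell's true geometry. Randomness is split per cell from the scene seed, so
results do not depend on iteration order, and identical configurations give
bit-identical scenes.

What the generator does *not* emulate: cell growth and division,
segmentation errors other than z-order occlusion, 3D structure, photophysics
beyond exponential bleaching, and any mechanistic coupling between a cell's
class label and its motion (class series are statistically independent
Markov chains riding on population-typical motion). Passing recovery tests
therefore demonstrates correctness of the measurement chain under the stated
generative model, not performance on real segmentation output.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 0-based frames, origin top-left, inherited by
  every module.
* Duplicate Voronoi seeds are perturbed by ε = 10⁻⁶ px with a warning;
  polygons are clipped to the field rectangle (corners at 0.5 and size+0.5,
  so pixel counting and polygon areas agree).
* Focus selection breaks sharpness ties towards the lowest plane index; the
  sharpness proxy is the variance of the high-pass residual.
* Offset estimation flags peak correlations below 0.5 as low-confidence
  (degenerate or unrelated images) instead of failing.
* Spot detection runs on the locally normalized (32 px window) sum of
  band-passed (difference-of-Gaussians, σ = 1 and 5 px) central planes, with
  subpixel positions from a 5 × 5 intensity-weighted centroid; thresholds are
  calibrated on synthetic data only, as the original detector's settings are
  not public.
* The acceptance-scale problem sizes (500 tracks × 100–200 steps for the
  exponent ensembles, 20-seed tessellations on 500 px fields, 60-frame
  120–400 px scenes) were chosen as the smallest sizes at which the
  stochastic checks are comfortably inside their sampling error.

## Pipeline and interfaces

Every user-facing function takes a data frame (or label matrix/stack) first
and returns a tibble, so stages chain with the pipe; fitted objects
(`directionality_alpha()`, `decay_time()`, `transition_matrix()`) have
`tidy()`/`glance()` methods and result rasters and histograms have
`autoplot()` methods. `run_pipeline()` executes simulate → track → spatial →
classify → motion → transitions → trails → prey from a YAML/JSON
configuration, writing TIFF/CSV/JSON artifacts plus a manifest with MD5
checksums; identical configuration and seed give identical checksums. A thin
Rscript wrapper (`inst/scripts/myxotrack-pipeline.R`) exposes the same entry
point from a shell, but the package functions are the primary interface.

## Known limitations

* No gap closing: a single missed link splits a track, which biases track
  lengths down in dense regions (fusions are flagged, not resolved).
* The Voronoi polygon of a multi-segment (branched) mask is taken at its
  longest segment's midpoint; other conventions are defensible.
* The illumination fit assumes an isotropic Gaussian centred near the field;
  heavily lysed fields distort it, so supply the measured profile when one
  exists.
* Trail "length" is reported as component pixel area; a skeletonized length
  variant would differ for wide shared patches.
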