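---
title: "polarTrack: models, measurements, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polarTrack: models, measurements, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarTrack)
```

# Scope

`polarTrack` quantifies the polar accumulation of a periplasmic fluorophore
(the motivating case is the *Pseudomonas* siderophore pyoverdin) in
time-lapse movies of bacterial microcolonies growing on an agarose pad. The
package has two halves that validate each other: a forward model that
simulates such movies with complete ground truth, and a measurement
pipeline (segmentation, per-cell geometry, long-axis profiles, pole/centre
ratios with a polarized/homogeneous classifier, lineage tracking, and
growth-resumption kinetics) whose every stage is tested against that truth
or against independent brute-force oracles. This vignette documents the
models, the conventions, the tunable parameters, and the choices made where
the design was genuinely open.

# The forward model

## Colony dynamics

Cells are 2D spherocylinders of fixed width (default 0.8 µm) on an
unbounded pad. Founder cells are placed either as a clustered inoculum spot
(default) or on a sparse regular grid (`placement = "grid"`, used for
calibration scenarios that require isolated cells). Each founder draws a
lag duration (normal, default 1.5 ± 0.5 h, truncated at 0); after its lag
it elongates exponentially in length,

$$L(t + \Delta t) = L(t)\, e^{r \Delta t},$$

and divides when it reaches the division length (default 4 µm) into two
daughters that share the mother's axis, with a ±5 % stochastic split
asymmetry. Exponential elongation is the standard single-cell growth model;
the default rate $r = 0.28\,\mathrm{h^{-1}}$ (doubling time ≈ 2.5 h) was
chosen so that an 18 h movie at 30 min frame spacing spans one lag
generation, one full exponential generation, and a final stationary
generation — the three-generation colony structure this kind of experiment
produces in succinate minimal medium. Faster rates would pack many more
generations into the movie and correspondingly harder tracking; both
regimes can be simulated, but the default is the realistic one.

Division stops when the colony reaches `carrying_capacity` cells
(stationary phase) or at an imposed `arrest_frame` (a chemical stressor
such as an iron chelator or a translation inhibitor). Each arrested cell
becomes polarized after a sampled onset delay (default 3 ± 1.5 h after
arrest), placing its focus at the new pole with probability
`new_pole_bias` (default 0.8). An optional `release_frame` models transfer
to a fresh pad: each polarized cell depolarizes after a sampled delay
(default 2 ± 0.75 h) and **only then** resumes elongation, so
depolarization always precedes regrowth in truth; non-polarized cells
resume immediately. `initial_polarized` starts a fraction of founders in
the polarized, division-arrested state, emulating cells stress-treated
before inoculation. A released colony that regrows to carrying capacity
re-enters stationary phase and its cells repolarize.

Overlaps created by growth and division are relaxed by pairwise hard-body
repulsion along centre-to-centre vectors (40 sweeps per frame over 7
sample points per cell axis). This is not a mechanical model of a dense
colony — cells do not slide frictionally or buckle — but it keeps masks
intact (worst-case pixel loss to neighbours is a few per cent) at the
colony sizes the package targets (≤ a few hundred cells).

All random draws come from deterministic per-cell sub-streams of the master
seed, so a configuration reproduces bit-identically and is independent of
the order in which cells are processed.

## Rendering

The fluorophore of a homogeneous cell lives in a thin periplasmic shell.
We render its 2D projection analytically: at distance $d$ from the medial
axis the projected column through a shell with outer radius $R$ and inner
radius $R_i$ is the chord difference
$2(\sqrt{R^2-d^2} - \sqrt{R_i^2-d^2})$, for the cylindrical flanks and the
spherical caps alike. By the hat-box property a thin spherical/cylindrical
shell carries *uniform fluorophore per unit axial length*, which is exactly
why a homogeneously fluorescent rod projects a flat long-axis profile and a
pole/centre ratio of 1; the small finite-thickness density deficit in the
cap slices is corrected analytically.

Two pixel-level effects still bias a naive shell rendering: the PSF bleeds
disproportionately much signal out of the mask at the cell tips, and the
measurement stage normalizes its axial coordinate on the *rasterized*
mask's principal axis, which differs from the generating axis by a fraction
of a degree. Both are handled by an axial flattening step: the candidate
weights are blurred with the rendering PSF on the local grid, their in-mask
axial mass profile is measured along the rasterized mask's own principal
axis in ~3 px bins (the bin count a multiple of 3, so equal mass per bin
implies equal mass per axial third), and the weights are rescaled per bin
(two rounds, gains clamped to [0.5, 3]). After this, isolated noise-free
homogeneous cells measure pole/centre ratios within about ±2 % across all
lengths and orientations; a flat 2 px boundary band, by contrast, would
inflate the ratio of a *homogeneous* cell to ≈ 1.17 because the pole thirds
contain more boundary pixels than the centre third.

A polarized cell relocates `focus_fraction` (default 0.5) of its
fluorophore into an isotropic Gaussian spot (σ = 0.15 µm) centred inside
the focus pole cap. A phase-contrast-like channel renders the projected
solid cell body; an optional reporter channel shares the pyoverdin
channel's spatial distribution (the co-localization scenario). Every frame
is convolved with a normalized Gaussian PSF (σ = 0.1 µm) using a circular
boundary, so total intensity is conserved exactly (the conservation test
holds to machine precision); optional Poisson shot noise and additive
Gaussian read noise (sd 2 counts) follow. Ground-truth label images assign
each pixel to the cell with the smallest normalized axis distance.

Units are arbitrary "counts": the real experiment's absolute fluorescence
scale is hardware-specific, and every downstream statistic in the package
is ratio-based by design. `periplasm_intensity` is defined as photons per
µm of cell length so that a cell's total fluorophore does not depend on how
its outline happens to rasterize.

# The measurement pipeline

## Segmentation and geometry

`segmentFrame()` smooths (Gaussian, σ = 1 px), thresholds (Otsu), refines
each object's boundary at a fraction (default 0.6) of its own
98th-percentile peak — the global threshold otherwise keeps the PSF halo —
and separates touching cells by a distance-transform watershed. It targets
the fluorescence channel, falling back to the phase-like channel for
non-producer strains. It is a deliberately simple stand-in for full
segmentation suites, adequate for the synthetic data and for well-resolved
real frames; ground-truth or externally produced label images can be
ingested instead (`readLabelStack()`).

`measureFrame()` reports 0-based centroids, principal-axis orientation in
$[0, \pi)$ (from the binary-mask covariance; near-isotropic masks with
aspect ratio < 1.2 — e.g. spherical mutants — use the intensity-weighted
covariance), axis length and width from pixel-projection extents (+1 px
for pixel footprint), per-channel intensity sums/means, and a QC flag:
`tiny` (area < 20 px), `boundary` (touches the frame edge),
`shape_anomaly` (solidity < 0.8), else `ok`. Only `ok` cells enter
downstream statistics; the thresholds are exposed because real pipelines
must filter segmentation errors but the right criteria are data-dependent.

## Profiles and the pole/centre ratio

`axisProfile()` projects mask pixels on the principal axis, min–max
normalizes to $[0,1]$, and averages intensities in `n_bins` (default 20)
half-open bins, the last bin closed; empty bins are linearly interpolated
and flagged. `pooledProfile()` averages profiles per bin and applies a
centred moving average (default window 3; window 1 is the exact identity).
When pole identity is known the convention is old pole at position 0.

`partitionThirds()` assigns pixels with axial coordinate in $[0, 1/3)$,
$[1/3, 2/3)$ and $[2/3, 1]$ to pole A, centre, and pole B.
`poleCenterRatio()` uses raw intensity sums without area normalization (an
area-normalized variant exists but is off by default). Cells with a
non-positive centre sum are excluded with a flag. Background handling is
per-frame median subtraction by default (clamped at zero), exposed as an
option because whether real acquisitions need it depends on the camera
offset.

## The classifier

A logistic discriminant on three features — max pole ratio, profile
peak-to-median, brightest-pole intensity fraction — chosen for transparency
and determinism: the maximum-likelihood fit is invariant to row order, and
the model serializes to a plain-text coefficient file. The default model
shipped in `inst/extdata/` is trained on simulator output with known states
under a fixed seed (`inst/scripts/make_default_classifier.R` regenerates
it). On held-out noisy simulations at focus fraction 0.5 its balanced
accuracy is ≈ 1; the package makes no claim about transfer to real images —
retrain on annotated data with `fitClassifier()` for that.

## Tracking and lineage

Masks are matched frame to frame in three steps: (1) confident mutual-best
continuations (IoU ≥ 0.65 — above the ≈ 0.55 bound a mother/daughter pair
can reach at ±5 % division asymmetry) are accepted outright; (2) a local
displacement field, interpolated from the five nearest accepted matches,
predicts where each remaining mask should now sit, and remaining
single-continuation and daughter-pair hypotheses compete greedily, scored
by (union) IoU times a Gaussian penalty (σ = 6 px) on the distance between
the flow-predicted mother centroid and the candidate (pair) centroid, with
area-ratio plausibility windows (a daughter is roughly half her mother; a
continuation is not); claims on masks that another unmatched cell explains
better are deferred to a later round; (3) a final unconstrained round and a
mutual-best rescue at low IoU settle leftovers, and gap closing re-finds
tracks across a single missing frame. `iou_min` (default 0.3) remains the
acceptance floor throughout. A naive greedy IoU matcher fails here
structurally: a daughter mask overlaps her mother at IoU ≈ 0.5 and would be
taken as a continuation, so divisions would never be seen.

Generations follow the observational definitions: F0 = birth unobserved,
division observed; F1 = daughter of an F0 that divided again; F2 = daughter
of an F1 that never divided and persisted to the final frame; everything
else `unassigned`. The daughter's axis end nearer the mother's centre at
division is the new pole, propagated frame to frame by end matching.
Elongation rate is the least-squares slope of log length against time over
the track's lifetime (the relative, per-hour rate; the absolute µm/h slope
is also emitted since either reading of "elongation rate" is defensible).
Ages count from birth, or from acquisition start for cells present at
frame 0.

## Kinetics

Lag time = first division frame × frame interval, censored at the horizon;
tracks not present from frame 0 are excluded. Depolarization time = first
frame from which the classifier label stays "homogeneous" for ≥ k = 2
consecutive frames (persistence against classifier flicker). Group
comparisons report n, median and quartiles (linear-interpolation quantiles,
R type 7, stated in the output metadata) and pairwise two-sided Wilcoxon
rank-sum tests on uncensored lag times; censored records are reported but
excluded from testing — no survival model is fitted, which is adequate at
the package's scale and stated here deliberately.

# What the simulator does and does not establish

The generator provides exact ground truth for polarization state, lineage,
pole identity, growth phase and kinetic times, so passing tests demonstrate
that the *measurement pipeline* recovers what the forward model encodes:
ratio computation bitwise-identical to brute-force pixel classification;
homogeneous nulls within ±5 %; classifier balanced accuracy ≥ 0.95 on
held-out noisy cells; frequency curves within ±10 percentage points of
truth; ≥ 99 % correct parent–daughter links on noise-free colonies at study
conditions; recovered kinetic medians within one frame interval.

They do not demonstrate performance on real micrographs. The simulator
omits: uneven illumination and background structure, focus drift,
photobleaching, cell curvature and septation intermediates, the mechanics
of dense multi-layer colonies, and segmentation error modes of real phase
contrast. The measurement conventions (thirds partition, ratio, profiles,
tracking definitions) transfer unchanged; the segmentation stage and the
shipped classifier should be treated as baselines to be replaced or
retrained for real data.

# Numerical choices and degenerate inputs

* Coordinates are 0-based, row-major (y, x); bounding boxes half-open;
  orientations in $[0, \pi)$.
* Thirds and profile bins are half-open with the last bin closed; a pixel
  landing exactly on a boundary belongs to the upper region, which is only
  defined up to floating-point ties.
* Zero-variance (single-point) axes raise errors naming the cell; empty
  foregrounds warn and return empty labelings; all-censored groups skip
  testing with a warning.
* The simulator aborts with a "runaway growth" error when the population
  exceeds four times the carrying capacity.
* The problem sizes used by the acceptance computations — colonies of
  ~40–55 cells over 36 frames, seven pooled replicate pads for the
  new-pole-bias estimate, 200 isolated cells for the calibration null —
  were chosen as the smallest sizes at which the binomial/recovery targets
  are statistically meaningful.

# Known limitations

* Tracking is near-perfect at the study conditions but not guaranteed
  beyond them: in very crowded colonies (≳ 150 cells) with synchronous
  division waves, occasional ambiguous events (~1 % of links) survive all
  of the matcher's constraints.
* The hard-body relaxation slightly under-resolves deep overlaps in dense
  colonies, so late-frame masks can lose a few per cent of their pixels to
  neighbours.
* The pole/centre ratio of a *short* cell (≈ 2 µm) is sensitive at the
  ±3–4 % level to half-pixel shifts of the thirds boundaries; this is a
  property of the statistic at this pixel size, not of the implementation.
* Cross-feeding of non-producers is modelled only as acquisition of the
  colony-mean fluorophore level scaled by `crossfeed_factor`; no transport
  mechanism is simulated.
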