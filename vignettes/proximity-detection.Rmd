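---
title: "Proximity-map regression for 3D cell-centre detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-map regression for 3D cell-centre detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `centrofind` computes, why its defaults are
what they are, and which choices were genuinely open when the package was
designed. It is the reference companion to the function documentation.

## The model

### From clicks to a regression target

A user annotates a cell class by drawing a rectangle on one 2D plane of a
volume and clicking the approximate cell centres inside it; a rectangle
with no clicks declares pure background. Each annotation becomes a
regression target over its region: the value at pixel $p$ is the **maximum
over the clicked points of a unit-peak Gaussian kernel**,
$\max_{pt} \exp(-\lVert p - pt\rVert^2 / 2\sigma^2)$. Two properties of
this construction carry the whole method:

* *Max, not sum.* Summing kernels would let the gap between two adjacent
  cells outscore either centre; the max keeps every local maximum of the
  target at a true centre, which is what allows touching cells to be
  resolved downstream.
* *Unit peak, not normalized density.* The kernel is an amplitude-1
  Gaussian rather than a probability density, so targets are bounded in
  $[0,1]$ and comparable across choices of $\sigma$. (A density kernel's
  peak would scale as $1/2\pi\sigma^2$, entangling the detection threshold
  with $\sigma$.)

$\sigma$ should be *smaller than the cell radius* — large enough to give
the regressor a learnable ramp, small enough that neighbouring cells'
kernels do not plateau into each other. For the 8-voxel-radius cells of
the bundled phantoms we use $\sigma = 4$. Kernels are truncated at
$3\sigma$ (value $e^{-4.5} \approx 0.011$ set to 0); the truncation is
part of the target definition and the test oracles apply it too.

### Features

Each pixel is described by a 2D multiscale filter bank computed per
channel: Gaussian smooth, Gaussian gradient magnitude, Laplacian of
Gaussian, and the two eigenvalues of the $2\times2$ Hessian, at
$\sigma = 1, 2, 4, 8, 16$ pixels, plus the raw intensity — 26 features per
channel. This scale range covers objects from a few pixels to a few tens
of pixels across and is deliberately not exposed as a routine tuning knob.
Multichannel volumes concatenate the per-channel banks, so the regressor
can integrate, say, a nuclear and a membrane marker.

Two open readings of "curvature eigenvalues" exist — Hessian or structure
tensor. We use the Hessian of the Gaussian-smoothed image: for bright
roughly isotropic blobs both eigenvalues are negative at the centre, which
is the directly useful signature. Whether the raw image belongs in the
feature vector is equally unstated in the density-counting literature; we
include it (it is nearly free and lets trees condition on absolute
brightness after normalization).

All features are computed strictly in 2D, per plane. The third dimension
enters only at the blob-detection stage; this keeps annotation 2D (fast
for the user) and training cheap, at the cost of the per-plane maps being
somewhat elongated in $z$ — which the 3D blob filter is there to resolve.

### The regressor

An ensemble of regression trees maps feature vectors to target values:
30 trees, maximum depth 10, minimum split 20 samples, $\lceil n/3 \rceil$
features considered per node, trained on a 1/5 subsample of the annotated
pixels (uniform without replacement, stratified per region). These
hyperparameters are deliberately modest — the intended regime is tens of
clicks on a handful of planes, and deeper forests mostly memorize noise at
that annotation budget. Fitting is delegated to `ranger`; note that
`ranger` interprets seed 0 as "randomize", so the package shifts all seeds
by one internally to keep seed 0 reproducible like any other.

Intensity is made comparable across acquisitions by rescaling each
`(t, channel)` sub-volume to $[0,1]$ between its 0.1 and 99.9 percentiles
before any feature computation; percentile clipping is robust to hot
pixels and saturated debris.

## From proximity maps to centres

Per-plane predictions are stacked into a 3D proximity volume, clipped to
$[0,1]$. Given expected object radii $h = (h_z, h_y, h_x)$ in voxels
(anisotropic voxel size is absorbed into $h_z$), the volume is smoothed
with an anisotropic Gaussian at scale $h/2$ and the determinant of the
$3\times3$ Hessian is computed at every voxel. For a bright blob all three
eigenvalues are negative, so $-\det$ is positive there and $\approx 0$ on
background, edges and ridges; we keep $\max(0, -\det)$. The factor $1/2$
in $h \to \sigma$ follows the same "scale slightly smaller than the
object" logic as the training kernel, and detection accuracy is flat for
$h$ within roughly $\pm 25\%$ of the true radius.

Centres are voxels that are strict maxima of the response within an
ellipsoidal neighbourhood of radii $h$ and exceed a threshold. The
threshold is expressed *relative to the per-timepoint maximum response*,
making it dimensionless and transferable across images; plateaus of
exactly equal response yield one detection at the rounded plateau centroid
(ties toward the lower index, for determinism). Because a relative
threshold always keeps the strongest maxima, `detect_centres` additionally
requires the proximity value at a detection to reach `min_peak`
(default 0.2): a true centre scores near 1 while a cell-free volume's
spurious maxima sit near 0, and this floor is what makes the detector
return *nothing* on background-only volumes.

Detections within $h$ of the volume border are kept but flagged — border
truncation biases both the response and the centroid, and downstream
counting may want to exclude them.

## ROIs, scoring, tracking, segmentation

**ROI interpolation.** Keyframed polygons are resampled to 100 points
uniformly by arc length, oriented counter-clockwise, starting at the point
nearest the +x direction from the centroid; corresponding points are then
interpolated linearly in $z$ and in $t$, clamping outside the keyframed
range. Arc-length correspondence from a canonical start is our answer to
the genuinely open question of how to pair vertices between keyframes of
different vertex counts; it behaves well for the convex-ish tissue
outlines ROIs are used for, and poorly for strongly non-convex shapes
(a documented limitation). Point-in-polygon uses the even-odd rule with
inclusive boundaries.

**Scoring.** Predicted and true centres are matched one-to-one among pairs
within the tolerance radius (optionally anisotropic), maximizing matches
and, among maximum matchings, minimizing total distance — a maximum-weight
bipartite matching (via `igraph`), not greedy nearest-first, so results
are order-independent and never understate F1 in crossing configurations.
Conventions: empty predictions and truth give precision = recall = 1
(vacuous); empty predictions against non-empty truth give precision 0.

**Tracking.** Frame-to-frame linking reuses the same optimal-matching
machinery on (predicted position, detection) pairs gated at `max_disp`,
with linear extrapolation across up to `max_gap` missed frames. The
division signal samples the "dividing" class proximity in a $3^3$
neighbourhood along a track, subtracts a centred moving average
(default 21 frames — wide enough to straddle one division pulse, narrow
enough to track slow background drift), and calls events at local maxima
exceeding 3 times the signal's median absolute deviation (unscaled MAD:
the signal is pulse-like, not Gaussian, so the 1.4826 normal-consistency
factor would inflate the threshold), separated by at least half a window.
The automatic event rule is a package design choice; with real recordings
the `signal` series should be inspected alongside the called events.
Cells with fewer than two called divisions are excluded from cycle-length
statistics, since a single division gives no interval.

**Segmentation refinement.** Detections become ellipsoids of radii $h$
(overlaps split by scaled nearest-centre), the binary union evolves 2–6
iterations (default 4) of a morphological Chan–Vese active contour (voxels
flip to the side — foreground mean vs background mean — they resemble
more, with one curvature smoothing pass per iteration), and marker-based
watershed on the inverted $h/2$-smoothed intensity re-partitions the mask
from the detected centres. Marker voxels are always retained, so the
output label count equals the detection count. The approach assumes
roughly round cells; elongated or branched objects are out of scope.

## The phantom generator

`generate_phantom` emulates the structure of clustered-nuclei benchmark
volumes: solid spheres (radius jittered ±10%) with Gaussian-soft edges
(blur $\sigma = r/4$), a configurable fraction of cells placed *touching*
an existing cell (centre distance ≈ sum of radii), the rest uniform
without overlap, constant foreground amplitude $A$ and additive Gaussian
noise with $\mathrm{SNR} = A/\sigma_n$. The default spec — 30 cells of
radius 8 in a $40\times128\times128$ volume, 75% clustering, SNR 5 — is
the package's standing model of a low-SNR, highly clustered 3D challenge
dataset; SNR 5 was fixed once as a realistic "low" signal-to-noise for
confocal live imaging and is not revisited per experiment.
`generate_division_series` adds scheduled divisions: a brighter, elongated
spindle figure for two frames (mitotic chromatin and spindle are brighter
in real movies — that contrast is what a "dividing" class learns), then a
persisting mother and a transient adjacent small daughter.

What the phantoms deliberately do **not** model: optics (PSF anisotropy,
depth attenuation), Poisson photon statistics, background structure,
non-spherical or deforming cells, and cell movement during division.
Passing the phantom benchmarks therefore demonstrates the machinery —
learning, 3D localization, separation of touching objects at low SNR —
but not robustness to optical artefacts; on real data the annotation
budget and the object-size parameter remain the user's responsibility.

## Study conditions computed by the tests and acceptance script

* Detection benchmark: train on 1 phantom (defaults above), tune the
  detection threshold on 5 phantoms over the grid
  $\{0.005, 0.01, 0.02, 0.05, 0.1, 0.2\}$ (ties resolved toward the more
  conservative, higher threshold), evaluate on 25; tolerances 4 voxels
  (strict) and 8 voxels (half a cell size, generous). Problem sizes were
  chosen to exercise the full pipeline at realistic density while keeping
  a complete run in minutes on one CPU.
* Division recovery: 5 single-cell series of 110 frames
  ($12\times48\times48$, radius 5), divisions scheduled every 22/23 frames
  — a 90-minute cycle at 4 min/frame; annotations built by
  `division_annotations` (spindle frames positive; daughter-phase and
  interphase frames background); window 21 frames.
* Training-level property: with 1 → 3 → 6 annotated planes, held-out F1 is
  non-decreasing within a ±0.05 noise band over 5 seeds — detection
  accuracy saturates at a modest annotation budget, which is the intended
  operating regime.

## Numerical choices

* Convolutions: separable sampled-Gaussian kernels truncated at
  $3\sigma$, symmetric (reflect) boundary padding everywhere; the
  order-2 kernel is DC-corrected so flat images have exactly zero second
  derivative. Reflect padding avoids the dark-frame artefacts of zero
  padding in small training regions.
* Plateau ties in maxima finding: centroid, rounded half toward the lower
  index. Determinism everywhere is treated as a contract: same inputs and
  seed give byte-identical outputs.
* Matching weights: edge weight $W - d$ with $W$ exceeding any achievable
  total distance, so cardinality strictly dominates distance.
* Serialization: detections store scores at 17 significant digits so the
  CSV round trip is exact; volumes round-trip bit-exactly for integer
  TIFF and at float32 precision for 32-bit output.

## Known limitations

2D features limit $z$-localization to what the blob filter can recover,
so strongly anisotropic voxels need $h_z$ set accordingly; the ROI
correspondence degrades on non-convex outlines; the division-event rule is
a heuristic intended for clearly pulsed signals; and the segmentation
refinement assumes convex, roughly spherical cells. Lineage assignment
(mother–daughter), drift registration and denoising are upstream or
downstream concerns outside the package's scope.
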