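---
title: "Quantitative whole-embryo phenotyping: models and methods"
author: "embryomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative whole-embryo phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryomorph)
```

## Overview

embryomorph implements a complete analysis chain for whole-embryo
phenotyping by optical projection tomography (OPT): sinogram axis
correction and filtered back-projection (FBP), intensity-based embryo
segmentation, 3D morphometry producing a 26-descriptor profile per
embryo, a PCA "morphospace" in which phenotypic severity organizes
embryos into clusters, and, on the confocal side, nuclear segmentation
and margin-distance signaling-gradient profiles. Because whole-embryo
imaging data are large and rarely deposited in desk-scale form, every
stage is paired with a synthetic phantom generator that produces inputs
with exact ground truth; all quantitative claims in this vignette are
the ones the package's tests and acceptance script themselves compute.

All volumes are `(z, y, x)` arrays with isotropic voxels (default
6.5 µm, the rendering resolution typical for 4x OPT of 24-hpf zebrafish
embryos) and 1-based indices in R; CSV exports are 0-based.

## The phantom generator

The phantom emulates a 24-hpf embryo body as a tube: a union of spheres
along a Catmull-Rom-interpolated centerline. The union-of-spheres
construction was chosen because it has an exactly known centerline (for
skeleton validation), an analytic volume for straight tubes (a
spherocylinder), and hemispherical ends — a flat-capped cylinder would
have a medial axis genuinely shorter than its length, which would make
centerline-length validation ill-posed.

When no control points are given the centerline is a planar circular
arc whose arc/chord ratio equals the requested tortuosity exactly (the
half-angle \(\alpha\) solves \(\alpha/\sin\alpha = \tau\)). The arc is
placed on integer-voxel z and y planes: an exactly half-voxel-centered
straight tube has a two-voxel-thick medial line on which *any* thinning
algorithm degenerates (we confirmed the same collapse in an independent
implementation before settling on this layout). Real embryos never have
this pathological symmetry, so this is a property of the fixture layout,
not a restriction of the method.

Severity is encoded by four independent knobs mirroring the descriptor
groups the pipeline measures: tortuosity (axis bending), sinusoidal
thickness modulation (thickness non-uniformity), axis-length scaling
(A/P shortening), and a surface notch (solidity reduction). The default
dose-response cohort has four levels x five embryos — the cohort sizes
used for dose-response OPT imaging of BMP-inhibited embryos — with
tortuosity means 1.03/1.17/1.31/1.45 (SD 0.02), thickness amplitudes
0–0.2, axis scales 1–0.72 and notch amplitudes 0–0.7, all varying
monotonically with dose level. Channel 1 carries uniform body intensity
(nuclear-stain-like), channels 2/3 carry Gaussian marker spots at the
centerline endpoints (head/tail expression landmarks). Optional noise is
additive Gaussian; all generators are pure functions of (spec, seed).

What the phantoms do *not* emulate: nuclear texture, yolk
autofluorescence, optical scattering and attenuation, or
embryo-to-embryo staining variability. Passing tests therefore
demonstrate the correctness of the geometry and of the computational
chain, not robustness to every artifact of real acquisitions.

## OPT reconstruction

Forward projection is parallel-beam (telecentric optics justify this):
line integrals sampled at one-voxel steps with bilinear interpolation,
at equally spaced angles over 360°, 400 by default. A miscentred
rotation axis is modeled as a lateral shift of the detector columns.
Mass conservation (projection sum = volume sum per angle, within
interpolation error) is asserted in the tests.

Axis-shift estimation registers opposite-side projection pairs
(θ, θ+180°), mirroring the second member, transforming both to the
Gaussian gradient modulus (σ = 30 µm ≈ 3 px at this sampling), and
taking the horizontal displacement at the 2D cross-correlation argmax;
the estimate is the median over 16 pairs. The mirrored opposite view is
displaced by exactly *twice* the axis offset (if the measured projection
is \(q_\theta(s) = p_\theta(s-a)\), the mirrored opposite view is
\(p_\theta(s+a)\)), so per-pair displacements are halved — a convention
we fix explicitly and cover with round-trip tests recovering injected
integer offsets −5..+5 px exactly. A 3-point parabolic sub-pixel
refinement is on by default; on noiseless phantoms it stays within
~0.25 px of the true offset. Correction translates all projections by
the negated shift with edge-value fill.

FBP is slice-by-slice: each detector row is ramp-filtered (Ram-Lak,
band-limited discrete impulse response, FFT implementation, zero-padded
to twice the detector width) and back-projected with linear
interpolation; the 360° angular range is retained and the sum scaled by
π/n. Negative ringing values are kept (downstream consumers clip if
they need nonnegativity). On a uniform cylinder the reconstruction
correlates with the phantom at r ≈ 0.985 with 400 angles, recovers the
disk radius within 1 voxel and the plateau amplitude within 5%;
fidelity degrades monotonically with fewer angles.

## Two-scale segmentation

The nuclear channel `U` is smoothed at three increasing scales
\(\sigma_1 < \sigma_2 < \sigma_3\) and combined into two normalized
difference images

\[ u_1 = \frac{U_{\sigma_1}-U_{\sigma_2}}{U_{\sigma_2}}, \qquad
   u_2 = \frac{U_{\sigma_2}-U_{\sigma_3}}{U_{\sigma_3}}, \]

blended and thresholded as \(w\,u_1 + (1-w)\,u_2 > t\). Denominators
are guarded by \(\varepsilon = 10^{-6}\max U\) because synthetic (and
dark-field) backgrounds are exactly zero. The normalization makes the
rule invariant to global intensity scaling, which the tests assert.
Components are labeled with 26-connectivity (standard for solid 3D
bodies) and instances pass a `[minSize, maxSize]` voxel-count window,
returned largest-first.

Defaults: \(\sigma\) = 13/39/117 µm (≈ 2/6/18 voxels), w = 0.8,
t = 0.8. The scale ordering is fixed by the method; the numeric w and t
were calibrated once on the default phantom geometry (Dice 0.97 against
the generator's true mask, with the segmented voxel count matching the
true count within ~0.1%) and are held constant across all samples of a
study — consistent with the practice of keeping segmentation parameters
fixed across embryos. Marker channels are never used for segmentation.

## Morphometry

**Landmarks.** Anterior/posterior anchors are the maximum-brightness
voxels of the head/tail marker channels within a 5-voxel dilation of
the mask; ties break to the lowest linear array index.

**Skeleton.** The mask is thinned to a curve skeleton by
border-sequential homotopic thinning: six directional subiterations per
pass; a voxel is deleted only if it is a simple point (topology
preserved, Bertrand–Malandain characterization: one 26-connected object
component in the 26-neighborhood and one 6-connected background
component touching a face neighbor) and not a curve endpoint.
Candidates within a subiteration are visited in order of increasing
distance to the background (exact Euclidean distance transform,
Felzenszwalb's algorithm), which keeps the surviving curve medial.
Pruning keeps the geodesic path (Dijkstra within the skeleton,
26-neighbor steps with Euclidean weights) between the two skeleton
voxels nearest the landmarks. Path length is measured on a 5-point
moving-average smoothing of the voxel chain, because the raw
26-connected chain overestimates curve length by staircase wiggle; with
this correction a straight tube measures 1.000 and a semicircular tube
1.570 ≈ π/2 in tortuosity (path length / endpoint chord).

**Descriptors.** 26 per embryo: voxel and µm³ volume; surface area
(exposed voxel faces x 2/3, the standard correction for digitized
smooth surfaces); sphericity; extent (volume / bounding box); solidity
(mask voxels / convex-hull voxels, hull built by an incremental 3D
algorithm with exact lattice-point counting); principal axis lengths
\(L_i = 4\sqrt{\lambda_i}\) from the coordinate covariance eigenvalues
(equivalent-ellipsoid convention; only the ratios enter the
morphospace, so the constant is inert) and their three ratios; skeleton
length and tortuosity; A/P chord; AP index; mean/variation (SD over
mean)/skewness/excess kurtosis of skeleton-to-surface distances
(thickness and its non-uniformity); the same four statistics of
in-mask intensity after subtracting the in-mask minimum; and centroid
depth (absolute and relative to the maximum in-mask depth). Moments are
population central moments (\(g_1 = m_3/m_2^{3/2}\),
\(g_2 = m_4/m_2^2 - 3\)); a constant value set reports variation 0 when
its mean is nonzero and NA (designated missing) when the mean is zero.

**AP index.** Pearson correlation between two distance maps over the
mask, seeded at the anterior and posterior landmarks. The maps are
*geodesic* within the mask rather than ambient Euclidean: embryos are
curved, and within-body distance respects the body. (Both map types are
computed by the same Dijkstra kernel; geodesic is the default and the
one used in the descriptor vector.) A straight elongated body gives
−1 (the two maps sum to a constant); coincident seeds give +1; folded
or shortened bodies move the index up from −1.

All shape descriptors are exactly translation-invariant and invariant
to axis-aligned 90° rotations within 2% — except the
distribution-shape moments of the skeleton-to-surface distance set,
which for a near-constant-calibre tube are dominated by discrete
resampling of the path and are therefore compared on an absolute scale
in the tests.

## Morphospace and severity clustering

Selected descriptors are z-scored and decomposed by PCA (SVD via
`prcomp`); the model stores means, scales, orthonormal loadings,
variance explained (eigenvalues of the feature correlation matrix as a
percentage of their sum, asserted against a dense eigendecomposition in
the tests), scores, and per-variable contributions to each component
(squared loading normalized to 100% per component, the convention of
the standard PCA-visualization toolchain). Component signs are fixed by
making the largest-magnitude loading positive, so results are
deterministic across platforms.

The default feature selection is the twelve scale-free shape
descriptors (sphericity, extent, solidity, axis ratios, skeleton
length, tortuosity, A/P chord, AP index, thickness mean and variation):
raw sizes and intensity moments mostly reflect acquisition settings
rather than morphology and, after z-scoring, near-constant intensity
moments would inject amplified noise. Both pooled fits and
fit-reference-then-project workflows are supported
(`projectSamples()` reproduces training scores exactly).

Clustering operates on the scaled descriptors by default (a flag
switches to PC-score space; whether the original analysis clustered in
descriptor or PC space is not documented, so the default follows the
convention of the clustering toolchain it mirrors). Methods:
hierarchical (Ward linkage on Euclidean distances; the default),
k-means (seeded, 10 restarts) and k-medoids (PAM, deterministic).
k = 4 by default — the four severity groups (unperturbed / slightly /
moderately / heavily perturbed) — fixed rather than selected
automatically. Labels are renumbered by ascending mean PC1 so cluster
ids order along the main severity axis; note that the PC1 *direction*
is sign-fixed by the loading convention, not by severity, so rank
correlations between cluster id and dose are evaluated in absolute
value. On the default four-level cohort all three methods recover the
generative dose labels with adjusted Rand index 1.0 and agree pairwise.

## Confocal gradient quantitation

Nuclei are segmented per optical section by adaptive local-mean
thresholding (box filter; the source protocol specifies "a mean filter"
without a radius, so the radius and an additive offset are exposed as
parameters with defaults of 5 px and 0), refined by one erosion and one
dilation with a 3x3 element, labeled in 3D across sections, and
filtered by a minimum voxel count. An optional per-section exclusion
region removes extraembryonic (YSL) nuclei before labeling. On the
synthetic stacks (50 well-separated Gaussian nuclei) counts recover
exactly across seeds and centroids land within 0.5 voxel.

Per-nucleus records (centroid, voxel count, per-channel mean intensity,
margin distance along the profiling axis, clamped at zero) feed a
lowess fit of intensity against margin distance per embryo, evaluated
on a common grid spanning the distance range shared by all embryos; the
group aggregate is the pointwise mean ± SEM. The smoothing fraction
defaults to 0.3 (the span used in the source analysis is not
documented). Local linear smoothing of an exponential is biased by
curvature ∝ (span x range / decay length)²; with the default span, a
~100 µm profiling range and a 40 µm decay length the fit stays within
2% of truth over the central 80% of the range, comfortably inside the
5% the acceptance suite requires. The domain-size ratio (signal domain
area / embryo area on the same maximum-intensity projection) replaces
manual polygon outlines with Otsu thresholds — of the embryo projection
first, then of the signal within the embryo region.

## Numerical choices and degenerate inputs

* Gaussian smoothing is separable with kernels truncated at 4σ and
  renormalized at array edges, so constants are reproduced exactly
  (hence `u1 = u2 = 0` for constant volumes, exactly).
* The distance transform is exact (squared-parabola lower envelope);
  skeleton-to-surface distances are measured to *surface voxels* (mask
  voxels 6-adjacent to background), matching the definition of the
  thickness descriptors.
* Convex hull: candidate extreme points are per-line min/max voxels;
  degenerate (coplanar) masks are an error. Lattice-point counting uses
  per-column half-space intersection with a relative tolerance of 1e-7,
  validated against Pick's theorem on an extruded polygon.
* Masks thinner than two voxels everywhere cannot be skeletonized
  (error); an all-constant projection series has no registration signal
  (error); fewer than 10 nuclei per embryo is an error naming the
  embryo; a constant in-mask intensity yields designated-missing
  scale-free moments, and rows containing missing descriptor values are
  dropped from the morphospace fit with a warning.
* Problem sizes in the tests and acceptance script — 48x64x96-voxel
  phantoms, 64–400 angles, 20-embryo cohorts, 200-nucleus stacks — were
  chosen as the smallest sizes at which the geometry is resolved well
  enough for the stated tolerances (e.g. tube radii of 7–10 voxels so
  that thickness variation is meaningful).

## Known limitations

* Parallel-beam geometry only; no cone-beam, attenuation, or flat-field
  modeling.
* The exact numeric segmentation parameters used in the original
  embryo study live in its supplementary material; the defaults here
  are calibrated on the phantom geometry and documented above.
* The 26-descriptor list reconstructs the named descriptors plus
  standard whole-object shape fillers; an exact one-to-one
  correspondence with the original array would require its
  supplementary definitions.
* Thinning-based skeletons are voxel-resolution objects: sub-voxel
  centerline accuracy is limited to roughly half a voxel, and exactly
  symmetric half-voxel-centered tubes are degenerate (see above).
* Lowess profile aggregation assumes embryos share a common distance
  range; embryos whose ranges do not overlap are an error rather than
  an extrapolation.
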