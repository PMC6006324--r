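---
title: "Joint space mapping: model, assumptions and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint space mapping: model, assumptions and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Joint space width (JSW) — the distance between the opposing outer cortical
bone surfaces of a joint — is a structural marker of joint disease, but at
clinical CT resolution it is frequently *below the resolution limit* of the
scanner: the point spread function (PSF) of a clinical acquisition is of the
order of 1 mm, and slice thickness is commonly 1.5 mm, while hip joint
spaces range from roughly 1.5 to 4.5 mm and can approach zero in disease.
Simple edge detection (thresholding) on such data conflates the blur with
the anatomy. jsmap measures JSW in 3D at sub-voxel precision by *modelling*
the blur and removing it through a constrained deconvolution at every vertex
of a joint space patch.

## The double-peak model

Along a ray crossing the joint, tissue density (in HU) is modelled as a
piecewise-constant five-level profile: femoral interior `y0`, femoral cortex
`y_peak`, joint tissue `y_js`, acetabular cortex `y_peak` again, and
far-side tissue `y3`, with edges `x0 < x1 <= x2 < x3`. The imaging blur is
taken as Gaussian with standard deviation `sigma` along the ray, so the
observed profile is a sum of Gaussian-CDF step terms (`model_profile()`),
and `JSW = x2 - x1` is the distance between the two *outer* bone surfaces.

Two constraints make the deconvolution stable where the peaks have merged:

* `y_js` is fixed at 35 HU, a cartilage-equivalent density;
* `y_peak` is fixed at a single global estimate of peak cortical density.

Everything else (`x0`, cortex widths, gap, `y0`, `y3`, `sigma`) is free and
fitted per vertex by bounded Levenberg-Marquardt least squares
(`fit_double_peak()`, via minpack.lm). Fitting widths rather than raw edge
positions enforces the edge ordering. With the peak density pinned, the
*area* under a blurred, attenuated cortical peak still determines its width
and position, which is what lets gaps below the PSF width be resolved.

Initialisation matters when the two cortical peaks have merged into one
bump. The fitter therefore runs a small multi-start: a seed from the
adaptive half-maximum method (resolved peaks), a seed that reads the
half-level support of the bright region as cortex + gap + cortex (merged
peaks), and a generic fallback; the lowest-residual converged fit wins, with
an early exit when a fit reaches numerical exactness. Absence of opposing
bone is decided *after* fitting: if the fitted acetabular plateau is so thin
relative to the fitted blur that its peak would be attenuated below 20% of
its height, or the outer edge sits at the sampling limit, the vertex is
flagged `no_opposing_bone` rather than given a spurious width.

## Peak cortical density

`estimate_peak_density()` fits a blurred single-cortex model with *free*
peak density at up to 1,000 randomly chosen vertices across the whole bone
surface and takes the **median** of the converged, quality-filtered
per-vertex peaks (amplitude at least 150 HU over the surroundings, cortex
width above 0.3 mm). On phantoms with known cortical density the converged
fits cluster tightly around the true value while failure modes skew low and
a few fits overshoot; the median lands within about 1% of truth, whereas an
upper-quartile aggregate overestimates by ~2-3%, and — because the fixed
peak constraint couples directly into the fitted widths — that error
propagates into a JSW bias of several hundredths of a millimetre. The
aggregate quantile is exposed as an argument for sensitivity analyses.

## Profile geometry and sampling

Profiles run along the outward vertex normal, `t` from -6 mm (inside the
femoral cortex) to +10 mm (beyond the largest expected gap plus acetabular
cortex) in 0.1 mm steps; interpolation is tricubic (Catmull-Rom) by
default, with trilinear as an option. Samples falling outside the grid take
the nearest-edge value and are flagged; profiles with more than 20% flagged
samples are rejected. The measurement only requires the initial femoral
surface to be within ±2 mm of the true surface: the fitted femoral edge
offset is part of the model, and the plausibility window on that offset is
the configurable `offset_limit` (2 mm).

## Patch construction

The femoral surface is extracted from the binary segmentation by marching
tetrahedra on a 1-voxel Gaussian-smoothed mask with gradient-consistent
outward orientation, followed by a few shape-preserving (Taubin) smoothing
passes. Opposing bone is projected onto the surface as the maximum HU
within 5 mm along each normal; the bright region's margin is where the
joint space patch boundary is drawn (in this package the boundary arrives
as a polyline, produced programmatically by the phantom module or by the
user). The patch is cut by snapping the polyline to mesh vertices, joining
them by shortest paths along edges, and flood-filling the enclosed side.

Re-triangulation to ~4,000 vertices uses midpoint subdivision followed by
greedy shortest-edge collapse. Collapses are allowed *along* the boundary
(onto existing boundary vertices, so the boundary curve is preserved as a
point subset) as well as in the interior; an earlier variant that froze
every boundary vertex left the rim ~8x denser than the interior, which in
turn dragged all neighbourhood-based smoothing towards the rim. Uniform
vertex density is a correctness property here, not an aesthetic one.

## Outlier removal and smoothing

False peaks in the fitted joint surface are flattened by masking vertices
whose femoral offset deviates from their 1-ring *median* (robust to pairs
of adjacent spikes) by more than 1 mm, refilling them from neighbours; at
most 10% of vertices may be altered. Error-based smoothing then runs 10
iterations in which each vertex moves towards the plain mean of its
neighbours with mobility `0.5 * (1 - w)`, `w = 1/(1 + (err/median err)^2)`.
The neighbour average is deliberately *unweighted*: weighting it by
reliability systematically biases the map wherever fit error correlates
with the signal, and on a narrowing joint space it does (small gaps are
harder to fit). A residual cost of any Laplacian-type smoothing remains:
at a local minimum of the width field (the narrowest part of a joint)
neighbour averaging can only pull values up, so a small positive bias at
the narrowest gaps is expected and visible in the phantom results below.

## The high-resolution reference (half-maximum method)

On data whose PSF is an order of magnitude finer than the structures, the
outer surfaces can be found without deconvolution: the local density peak
nearest the vertex is the femoral surface; the threshold is half the peak
*amplitude above joint tissue* (i.e. `(peak + y_js)/2`), whose outward
crossing is the femoral outer edge, since for an isolated blurred step the
half-amplitude crossing coincides with the true edge; the next peak above
that threshold provides the acetabular edge the same way. No smoothing is
applied, and technical failures are removed by fixed positional (2 mm) and
value ([0.2, 10] mm) limits in place of the interactive review the
measurement was originally paired with. The threshold choice relative to
`y_js` rather than zero is an interpretation: it is the variant for which
the analytic edge property holds exactly.

## Registration

Volumes are aligned by maximising mutual information of a 64-bin joint
histogram over a 7-degree-of-freedom similarity transform, with a
multiresolution pyramid, a translation-only pre-stage and restarted
Nelder-Mead at each level. Surfaces are aligned by ICP with scale
(Umeyama updates, multi-start from centroid and principal-axis
initialisations) followed by a thin plate spline (kernel `U(r) = r`,
lambda 0.01 by default, 200 farthest-point control points); the TPS stage
is discarded if it does not reduce the residual. Per-vertex values move
between surfaces by nearest-vertex transfer with an optional smoothing
pass. The average surface is built by registering every contributor to a
re-triangulated reference and averaging nearest-correspondent positions in
the *world* frame (so no contributor's pose is privileged), for two
refinement iterations, with Taubin smoothing in the interior and
shrink-compensated smoothing along the boundary. Registration accuracy
affects only cross-source comparison, never the measurement itself.

## Agreement statistics

Accuracy is the mean of method A minus method B over vertices valued in
both; precision is the sample SD of those differences; limits of agreement
are 1.96 x SD; RMSCV is `100 * sqrt(mean(CV^2))` with per-pair
`CV = SD/mean` and the two-value sample SD `|a-b|/sqrt(2)`. Sample (n-1)
SDs are used throughout. Reference data can first be trimmed to their
central 95% (type-5 linear-interpolation percentiles, boundary values
retained); a trimmed vector carries its bounds so re-trimming is a no-op.
Per-vertex maps apply the same formulas across subjects at each vertex of
a common surface, masking vertices with fewer than 3 contributors.

## The phantom generator

Synthetic phantoms are the package's ground truth: two parallel cortical
plates, or a spherical femoral head (radius 20 mm, cortex 1.5 mm) capped by
a concentric acetabular shell over a 60 degree polar cap with a horseshoe-like
uncovered margin, joint tissue fixed at 35 HU, cortex 1400 HU, interior
300 HU, soft-tissue background 50 HU. The gap is a constant or a smooth
angular function; the clinical validation phantom raises it from 1.5 mm at
the pole to 4.5 mm following `1 - cos(theta)`, which distributes patch area
approximately uniformly across gap values and keeps the narrowest gaps
facing the worst-sampled (slice) direction. Defaults mirror a clinical hip
protocol: 0.31 x 0.31 mm pixels, 1.5 mm slices, PSF 0.87 mm in-plane and
1.00 mm out-of-plane read as FWHM (a configuration switch treats them as
sigma instead), noise SD 20 HU.

Voxelization samples the continuous geometry on a supersampled grid
(factor 3 per axis by default, odd by construction), then applies, per
axis, the *composite* kernel — Gaussian PSF convolved with the voxel
box — evaluated only at coarse voxel centres. This is the physical
acquisition order (object, then blur, then detector integration), and it
makes the realised edge spread match the closed-form
`sigma_eff = sqrt(sigma_psf^2 + h^2/12)` model to a fraction of an HU,
which the test suite verifies against an erf-fit oracle. Noise is iid
Gaussian, seeded; identical specs give bit-identical volumes. What the
phantom does **not** emulate: trabecular texture, beam hardening,
correlated CT noise, cartilage layering, or realistic acetabular anatomy —
so passing the phantom suite demonstrates correctness of the measurement
chain under the stated physics, not clinical performance.

Two-operator variability is simulated by perturbing the joint-margin
boundary tangentially along the femoral sphere with a smooth low-order
Fourier displacement of chosen RMS amplitude (2 mm in the reproducibility
run), mimicking disagreement in margin definition, which is where operator
variance is expected to concentrate.

## Problem sizes and numerical choices

The shipped validation runs use a radius-20 mm ball-and-socket phantom at
clinical spacing (about 200 x 200 x 38 voxels), patches of 900 (test
suite) or 1,500 (acceptance script) vertices, and 400-1,000 vertex
subsamples for peak density estimation; these sizes give stable statistics
while keeping a full run in minutes on one core. Optimiser settings:
Levenberg-Marquardt, at most 200 iterations, cost tolerance 1e-8, sigma
bounded to [0.1, 3] mm. Ties and degeneracies: constant volumes make
mutual information identically zero and are refused with a warning;
coplanar TPS control points are refused; an all-masked outlier pass is an
error rather than an empty map.

## Known limitations

* At gaps near the slice thickness measured along the slice axis, the
  Gaussian blur model is only an approximation to box-integrated sampling,
  and a residual overestimation of order 0.1-0.2 mm remains at the
  narrowest, worst-oriented gaps (the global phantom bias stays under
  0.1 mm). This mirrors the behaviour reported for the method on real
  cadaveric validation data.
* The fixed 35 HU joint tissue density is appropriate for cartilage;
  effusion or contrast would shift it.
* ICP-based surface registration assumes shapes distinctive enough to lock
  rotation; near-rotationally-symmetric patches rely on the principal-axis
  multi-start.
* The half-maximum reference requires sampling at or below 0.1 mm and is
  meaningful only when the PSF is much narrower than the structures.
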