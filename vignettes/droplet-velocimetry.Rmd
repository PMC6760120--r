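---
title: "Measuring flow and aggregate morphology around a pinned micro-droplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flow and aggregate morphology around a pinned micro-droplet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microptv)
```

## The measurement problem

A crude-oil micro-droplet rising through sea water is, in the frame of the
drop, a stationary obstacle in an oncoming flow. When such a drop is pinned
between the walls of a shallow microchannel and a bacterial suspension is
pumped past it at the Stokes rising speed of an equivalent free drop
(`stokes_rise_velocity(150, 150)` = `r round(stokes_rise_velocity(150, 150), 2)`
mm/s for a 150 µm drop of ~850 kg/m³ oil in water), the suspended cells
themselves become flow tracers. A high-speed camera (1000 fps for 1 s bursts)
images a 720 × 720 µm field of view at 0.70 µm/px
(`pixel_pitch(720, 1024)` = `r round(pixel_pitch(720, 1024), 3)`), and a
second, time-lapse stream (30 s interval) follows the polymeric aggregates
that the bacteria build on the oil-water interface over days.

This package implements the full quantitative chain for both streams:

1. **micro-PIV** — window cross-correlation of consecutive frames, giving a
   coarse predictor displacement field;
2. **PIV-assisted PTV** — per-cell detection and frame-to-frame matching
   guided by the PIV predictor, giving one velocity vector per tracked cell;
3. **Taylor-expansion gridding** — local least-squares interpolation of the
   pooled unstructured vectors onto a regular 4 px (2.8 µm) grid;
4. **hydrodynamic maps** — nondimensional velocity, viscous-stress and
   streamwise momentum-budget maps with an inferred pressure gradient;
5. **morphometrics** — drop geometry, film-thickness-versus-angle profiles,
   and streamer-tail extent from the time-lapse stream.

Because no experimental imagery is distributed, a synthetic-scene generator
renders tracer image sequences over analytic ground-truth flows, so that
every stage — and the chain end to end — is verifiable against a known
field.

## The ground-truth flow model

Two-dimensional Stokes flow past a cylinder has no bounded solution (the
Stokes paradox), but the channel here is shallow (~100 µm), so the
depth-averaged Hele-Shaw limit applies, and the mid-plane field around the
circular cross-section is potential flow past a circle. With drop radius
$a = D_d/2$ and free stream $U_f$ along $+x$, in drop-centered polar
coordinates:

$$u_r = U_f\left(1 - \frac{a^2}{r^2}\right)\cos\theta, \qquad
  u_\theta = -U_f\left(1 + \frac{a^2}{r^2}\right)\sin\theta .$$

This field is divergence-free, satisfies no-penetration on the perimeter
(`evaluate_flow()` refuses points strictly inside the drop), vanishes at the
leading stagnation point and reaches $2 U_f$ at the poles $\theta = \pm\pi/2$.
It does **not** satisfy no-slip on the perimeter — it is an analytic oracle
with a drop-shaped obstacle, not a solution of the full three-dimensional
problem. A `potential_plus_wake` variant subtracts a Gaussian streamwise
deficit downstream to emulate the momentum defect behind trailing aggregates.
Tracers are advected by midpoint (second-order Runge–Kutta) integration with
the frame interval as time step — per-frame displacements are a few pixels,
so higher-order integration gains nothing — plus an optional Brownian step of
per-axis variance $2 D\,\Delta t$; tracers that would penetrate the drop are
reflected specularly off the perimeter and counted.

Rendering integrates a Gaussian point-spread profile (σ = 0.7 µm by default)
over pixel areas, adds a dark drop footprint (attenuated interior, darker
rim), seeded Gaussian read noise, and clips to the 16-bit sensor range. The
5 µm depth of field of the real optics is modeled as purely two-dimensional:
tracers live at the focal mid-plane, and out-of-plane motion is out of scope.
What the generator does **not** emulate: DIC optical contrast, rod-shaped
cell appearance (available as an option, unused by the tests), swimming
motility, aggregate growth, and illumination drift. Passing the synthetic
tests therefore validates the measurement chain's geometry and statistics,
not its robustness to every optical artifact of real micrographs.

The default scene mirrors the experiment: 720 × 720 µm on 1024 × 1024 px, a
150 µm drop at frame center, $U_f$ = 2000 µm/s, 1000 fps, and 600 tracers in
view. The experiment's stated cell concentration (~10⁶ cells/ml) and
per-frame count (~1000) are mutually inconsistent for a 720 × 720 × 5 µm
slab, so the generator parameterizes the in-view count directly. For bursts,
the seeding box is extended upstream by the free-stream drift over the burst
duration, which keeps the in-view density stationary exactly as continuous
upstream seeding does in the channel.

## PIV engine

`correlate_pair()` uses 32 px windows at 50% overlap (standard µPIV practice
at this seeding density; the original acquisition protocol names no window
parameters).
Equal-size windows are mean-subtracted and correlated directly over a
±8 px search range, each lag normalized by its overlap area (the unbiased
estimator) and by the window energies. Equal windows make the
autocorrelation plane exactly symmetric — identical frames give identically
zero displacement, and swapping frame order negates the field exactly —
which a margin-extended second window would break. Sub-pixel displacement
comes from a three-point Gaussian fit per axis, falling back to a parabolic
fit when a neighbor correlation value is non-positive; peaks on the search
border are rejected. The primary/secondary peak ratio (3 × 3 exclusion zone)
must exceed 1.2.

Windows with more than half their pixels inside the excluded region are
masked a priori. The exclusion mask passed by the burst pipeline is the drop
footprint **dilated by 6 µm**: the dark rim is a stationary image feature, and
any window that sees it correlates to zero displacement regardless of the
tracers moving through it. Validation is the normalized-median
(universal-outlier) test over 8-neighborhoods with a 0.1 px noise floor;
masked interior holes are refilled with the neighborhood median and flagged.
The predictor is interpolated bilinearly, clamped at the lattice hull, with
a nearest-valid-node fallback within two lattice steps near masked regions —
particles deeper inside the mask are skipped and counted.

## PIV-assisted PTV

Detection is difference-of-Gaussians band-pass filtering (σ = 1 and 2.5 px),
strict local maxima above a robust threshold (median + 5 MAD, with an
absolute floor against floating-point ripple on flat frames), brightest-first
minimum separation of 3 px, and sub-pixel refinement by intensity-weighted
centroid over a 7 × 7 window of the non-negative band-pass response. Spots
whose refinement window is clipped by the frame border are discarded —
truncation biases the centroid toward the interior. Detections with a close
neighbor are re-centroided after subtracting the neighbors' modeled Gaussian
response; partially overlapping spots otherwise pull each other's centroids
together, and in near-uniform flow that bias is persistent rather than
averaging away. Tracers at contact distance (< 3 px) merge into a single
detection; that is a physical resolution limit, not a defect the matcher can
undo.

Matching projects each first-frame particle by the interpolated predictor and
ranks candidate partners within a 3 px radius by residual; assignment is
greedy in ascending residual under a one-to-one constraint. With a good
predictor the assignment problem is near-diagonal, so greedy resolution is
$O(n \log n)$ and, unlike plain nearest-neighbor linking, does not swap
neighboring particles sheared past each other. Multi-frame trajectory
stitching is deliberately absent: the measurement uses frame-pair velocities
only.

## Taylor-expansion gridding

`taylor_grid()` fits, at each node of the drop-centered 4 px grid, all
vectors within three grid spacings by weighted least squares to a local
Taylor polynomial (order 2 by default — second order is needed to follow the
curvature near the drop; order 1 is available), with Gaussian distance
weights of scale half the neighborhood radius. The node value is the
constant term, which makes the scheme exactly polynomial-reproducing up to
the chosen order — the property the test suite freezes at 10⁻⁸. Offsets are
scaled by the radius for conditioning.

Three guards keep the local fits honest, all of them masking (never
repairing) a node:

* **sample count** — fewer than twice the number of polynomial coefficients
  within reach masks the node;
* **support** — samples must occupy at least three of the four quadrants
  around the node; otherwise the "fit" is an extrapolation (frame edges,
  mask rims) that amplifies noise;
* **conditioning** — each Cholesky pivot of the normal equations must retain
  at least 2% of its original diagonal. This rejects degenerate geometries
  such as all samples on one ring (quadratically rank-deficient) or in two
  thin streamwise bands, where the healthy-geometry pivot ratio (~0.1 and
  above, measured on uniform disk samples) collapses by two orders of
  magnitude.

One robust refit pass discards samples whose residual exceeds three times
the weighted RMS — the occasional wrong PTV match — and refits. Vectors from
all frame pairs are pooled before gridding (the default; `ensemble_merge()`
supports gridding pair-wise and averaging with sample-count weights
instead). A "4 pixel (2.7 µm)" grid spacing is sometimes quoted for this
measurement, which is internally inconsistent with 0.70 µm/px optics
(4 px = 2.8 µm); the grid here is defined in pixels and the metric spacing
follows from calibration.

## Nondimensional hydrodynamics

Lengths are scaled by $D_d$, velocities by $U_f$, stresses by
$\mu_f U_f / D_d$, and $Re_{D_d} = \rho_f U_f D_d / \mu_f$ weights the
inertial term (0.3 for the default scene). When $U_f$ is not supplied it is
estimated as the median streamwise velocity over the upstream 10% of valid
columns, which is robust to wake structure and streamers downstream.

The streamwise momentum balance implemented is

$$Re_{D_d}\,(\vec u^* \cdot \vec\nabla^*)\,\vec u^* + \vec\nabla^* p^*
  - \vec\nabla^* \cdot \vec\nabla^* \vec u^* = 0,$$

from which the pressure gradient is inferred node-wise as
$\partial p^*/\partial x^* = \mathrm{viscous} - \mathrm{inertial}$. The
balance closes by construction, so the stored diagnostics are term
magnitudes, not a closure residual. The two map quantities
$\tau^*_{xx} = \partial^2 u^*/\partial x^{*2}$ and
$\tau^*_{xy} = [\partial^2 u^*/\partial y^{*2} +
\partial^2 v^*/\partial x^{*2}]/2$ are computed exactly as defined in the
measurement convention this package follows; note that dimensionally they
are components of the viscous force density
$\vec\nabla^* \cdot \vec\nabla^* \vec u^*$, not of the stress tensor — the
names are kept, the formulas are verbatim. Derivatives are second-order
central differences with second-order one-sided stencils at mask edges and
no pre-smoothing (the gridding already regularizes); nodes lacking a full
stencil are masked.

Two closed-form checks anchor the budget. On the upstream stagnation line
the doublet gives $u^*(x^*) = 1 - (1/2)^2/x^{*2}$, the velocity components
are harmonic (so the viscous term is analytically zero), and the inferred
gradient must match the Bernoulli form
$-Re_{D_d}\, u^*\, \mathrm{d}u^*/\mathrm{d}x^*$. The agreement band is 10%
for nodes at least a quarter diameter clear of the perimeter: closer in, the
fourth-derivative truncation error of the discrete Laplacian (the dominant
error term at $h^* \approx 0.019$) exceeds that. Second, as
$Re_{D_d} \to 0$ the pressure-gradient map equals the viscous map to machine
precision. A mirror-symmetry check verifies that $u^*$ even / $v^*$ odd in
$y^*$ propagates to an even $\tau^*_{xx}$, an even
$\partial^2 u^*/\partial y^{*2}$ and an odd
$\partial^2 v^*/\partial x^{*2}$ — the composite $\tau^*_{xy}$ itself has no
definite parity, since it sums an even and an odd part.

The Stokes utility uses the rigid-sphere law
$U = \Delta\rho\, g\, d^2/(18\mu)$ rather than the Hadamard–Rybczynski
mobile-interface form: crude oil is far more viscous than water, so the
rigid limit applies, and it reproduces the 2 mm/s working figure (1.84 mm/s
at one significant figure).

## Morphometrics

`fit_drop()` finds the dominant dark disk, casts 360 radial intensity
profiles from its centroid, locates the perimeter per ray as the sub-pixel
mid-level crossing, and fits a circle (Kasa algebraic fit refined by
Gauss–Newton on geometric distance), reporting the RMS radial residual. Two
passes of edge re-extraction make the fit center-independent. Aggregate
segmentation is local-background-relative: robust z-score above 2 in either
direction, with background statistics estimated outside the drop. Relative
thresholds make every metric invariant to affine intensity transforms; no
trained model is involved, because the fixtures must validate the procedure
analytically and DIC contrast is not modeled.

Film thickness is measured along radial rays at 1° resolution — the
thickness is the outermost extent of the mask run anchored at the perimeter,
bridging holes up to 2 px — then binned (72 bins of 5° by default, bin
centers at multiples of the width so ±45° are exact centers). Angles are
measured from the leading stagnation point, positive counterclockwise, with
the flow axis declared in configuration; co-rotating the axis co-rotates the
profile. The tail metric keeps aggregate components connected to the
perimeter, projects them on the flow direction, and reports the farthest
connected extent beyond the rear perimeter in µm and drop diameters, with a
width profile and a hollow fraction (one minus the area ratio to the filled
mask). The fixtures mirror the three observed regimes: a ~4 µm uniform film,
~50 µm crescents peaked at ±45° from the stagnation point, and a
12-drop-diameter streamer tail (classified against the ">10 diameters"
criterion). Segmentation thresholds are fixture-validated conventions; the
original observations were visual and published no segmentation procedure.

## Reproducibility and problem sizes

Every run is seeded: one master seed fans out to per-module child seeds by a
fixed linear-congruential derivation, so module-level reruns are
independently reproducible and a rerun of any command with identical inputs
produces byte-identical artifacts (checksummed in a manifest). The test
suite validates the full chain on a 100-frame burst at the experiment's
geometry and density (the ~4-minute end-to-end check, where the gridded
speed field must stay within 5% of $U_f$ of the analytic field outside a
10 µm annulus), and exercises units on a desk-scale 256 px / 180 µm window
with a 60 µm drop at the same pixel pitch and areal tracer density. Sizes
were chosen so the whole suite validates the same physics at a few minutes'
cost.

## Known limitations

* The oracle flow is the Hele-Shaw potential limit: no no-slip layer on the
  perimeter, no three-dimensional structure, no interface mobility.
* Single-pass PIV with a ±8 px search: flows with per-frame displacements
  beyond that need a larger search or a faster frame rate, not window
  deformation (deliberately out of scope for a predictor field).
* Sub-pixel PIV estimates on sparse windows (a few spots) carry estimator
  noise of order 0.1 px; the PTV stage, not the PIV field, is the
  measurement.
* No pressure-Poisson integration: only the gradient is inferred, as the
  balance defines it.
* Aggregate segmentation assumes aggregates deviate from a roughly uniform
  background; strongly textured backgrounds would need a different model.
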