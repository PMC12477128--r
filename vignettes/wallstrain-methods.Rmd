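---
title: "Aortic wall strain from cine ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic wall strain from cine ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallstrain)
```

## The measurement problem

Abdominal aortic aneurysms (AAA) are dilations of the abdominal aorta whose
rupture risk is managed today almost entirely by diameter surveillance.
Diameter, however, is an indirect proxy for the state of the wall itself.
Ultrasound elastography offers a complementary, mechanics-based marker: the
wall of the aneurysm deforms over each cardiac cycle, and the magnitude of
that deformation per unit of driving pressure reflects wall compliance. A
stiff, collagen-remodeled wall deforms little; an inflamed, degraded wall
deforms more.

`wallstrain` implements the full measurement chain for one scalar biomarker:
the **peak mean tensile principal wall strain normalized by pulse pressure**,
written eps/PP and reported in percent per mmHg. For a cross-sectional cine
loop spanning one cardiac cycle (end-diastole to end-diastole):

1. the operator supplies a two-contour wall region of interest (inner and
   outer wall) on the end-diastolic reference frame;
2. a four-node quadrilateral finite-element mesh is laid over the wall;
3. nodal displacements are tracked frame to frame by regularized non-rigid
   intensity registration and accumulated over the cycle;
4. each element's Green-Lagrange strain yields its tensile principal strain;
   the area-weighted wall mean per frame gives a strain curve whose maximum
   is the peak mean principal strain eps (a dimensionless fraction);
5. eps is normalized by the brachial-cuff pulse pressure:
   eps/PP = 100 * eps / (systolic - diastolic), in %/mmHg.

The cohort layer pairs index and follow-up visits, stratifies patients into
strain terciles at fixed cutoffs, computes annualized change rates, and runs
the nonparametric comparisons appropriate to small, non-normal samples.

## Strain model

Strain is **total Lagrangian**: all displacements are expressed relative to
the end-diastolic reference configuration, and the strain measure is the
Green-Lagrange tensor `E = (F'F - I) / 2` with `F = I + du/dX`. Green strain
is exactly invariant to rigid rotation, which matters because a pulsating,
possibly translating vessel section rotates elements appreciably; the
infinitesimal tensor is available behind `measure = "infinitesimal"` for
comparison but is not the default. Per element, `F` is evaluated once at the
element centre from the bilinear shape-function gradients. The element's
scalar summary is the **larger (tensile) principal strain**, the positive
eigenvalue branch

eps1 = (Exx + Eyy)/2 + sqrt(((Exx - Eyy)/2)^2 + Exy^2),

and the per-frame wall summary is the element-area-weighted mean of eps1,
with areas taken in the reference configuration. Area weighting (rather than
a plain element mean) makes the summary insensitive to meshing density.

Two exactness properties pin the implementation down and are enforced in the
test suite: any affine displacement field is reproduced exactly on any valid
mesh (patch test, 1e-10), and rigid rotations produce strain below 1e-12.

## Meshing

Both ROI contours are resampled to `n_circumferential` arc-length-uniform
points starting at the point of maximum x (a deterministic start rule, so
meshing is reproducible across sessions), and `n_radial + 1` node layers are
linearly interpolated through the wall. Elements are quadrilaterals with
counterclockwise node order; the builder verifies a positive Jacobian at the
element centre and all four Gauss points and rejects inverted elements by
index. Coordinates are image-physical millimetres with the origin at the
top-left pixel centre and y increasing downward; everything is 0-based.

The default resolution, 48 x 3 elements, resolves the wall of a typical
aneurysm cross-section (elements of roughly 1.5 x 1.3 mm at a 24-28 mm
diameter) while keeping per-element speckle content high enough to track.
Mesh-total area converges to the analytic annulus area under refinement; at
64 x 4 on circles the area error is below 1%.

## Displacement tracking

One increment between consecutive frames minimizes

(1/P) sum_p [ I_b(X_p + u_p(d)) - I_a(X_p) ]^2
  + lambda * (1/M) sum_(ij) |d_i - d_j|^2 / L_ij^2

over nodal increments `d`. The intensities `I` are locally mean/variance
normalized (9 px windows), which makes the match robust to gain differences;
sample points `X_p` are a 5 x 5 per-element grid interpolated with the
element shape functions; the membrane penalty runs over mesh edges with
squared edge lengths `L_ij^2` in the denominator, so it approximates the mean
squared spatial *gradient* of the increment field and `lambda` is
dimensionless and mesh-independent. The solve is coarse-to-fine on a 3-level
anti-aliased pyramid with L-BFGS-B and an analytic gradient; increments
start at zero, iteration caps are fixed (50/level), and there are no
stochastic steps, so tracking is deterministic. Both frames are first passed
through a 5-tap binomial filter: B-mode speckle lives close to the Nyquist
limit and unfiltered bilinear interpolation of such texture carries a
systematic subpixel bias that the filter largely removes.

Displacements accumulate by sequential composition: frame k's displacement
is frame k-1's plus the increment estimated at the currently displaced node
positions. Composition alone, however, lets small per-increment errors
compound: on phantom ladders this inflates low-strain estimates (noise in
the displacement field enters the tensile principal strain with a positive
bias, since the larger eigenvalue is a convex function of the tensor) and
drifts at loop closure. `track_cycle()` therefore, by default, refines each
composed displacement with one direct registration of frame k against the
reference frame, warm-started at the composed estimate
(`refine_to_reference = TRUE`). The frame-to-frame pass supplies the
initialization that makes the direct solve tractable; the anchored
refinement stops the compounding. On the phantom suite this cuts
loop-closure drift from ~15% to ~1-5% of peak RMS displacement and brings
biomarker recovery within a few percent across the tested strain range.

`lambda = 8` is the package default, chosen by an L-curve sweep on the
phantom ladder: smaller values leave displacement noise that biases
low-strain estimates upward; much larger values visibly shrink true strain
gradients. Registration quality is reported per frame as the mean local
normalized cross-correlation between reference samples and warped moving
samples; an iteration-capped solve flags `converged = FALSE` rather than
erroring.

## The synthetic cine phantom

No patient data ships with the package, so validation rests on a phantom
with analytic ground truth. The phantom is a thick-walled annulus (defaults:
inner radius a0 = 10 mm, outer b0 = 14 mm — a mid-sized AAA cross-section)
pulsating under a raised-cosine pressure waveform that is diastolic at both
cycle ends and systolic exactly once, at 35% of the cycle. Wall kinematics
are the plane-strain, area-preserving radial map

r'(r, t) = sqrt(r^2 + a(t)^2 - a0^2),

the simplest incompressible-wall model with closed-form strain: the in-plane
stretches are r'/r (circumferential, tensile) and r/r' (radial), so the
larger principal Green strain is ((r'/r)^2 - 1)/2 and its area-weighted wall
mean has the closed form `c * ln(b0/a0) / (b0^2 - a0^2)` with
`c = a(t)^2 - a0^2`. `a_peak_for_mean_strain()` inverts this so phantom
ladders can be specified directly by target peak mean strain. An optional
"stiff sector" scales radial displacement by a compliance factor over an
angular span (10-degree cosine taper); its ground-truth mean strain is
evaluated by polar midpoint quadrature of the exact deformation gradient,
and a compliance of 1 reproduces the homogeneous phantom bit-for-bit.

Speckle is simulated at the envelope-intensity level: scatterers placed
uniformly at random (8 per mm^2), each with Rayleigh amplitude and uniform
phase, are advected by the ground-truth displacement field — the texture
warps and is never regenerated, so frame-to-frame correlation is trackable —
then splatted onto the pixel grid as a complex field, blurred by a Gaussian
point spread (sigma 0.3 mm), envelope-detected, log-compressed, scaled to
[0, 1], and degraded with additive Gaussian noise (sigma 0.02 intensity
units) after compression. Frames are quantized to float32, the on-disk TIFF
sample format, so loops survive write/read round trips bit-identically.
Everything is deterministic given the seed.

What the phantom does **not** emulate: radio-frequency data and beamforming
(the registration here operates on envelope intensity), attenuation and
shadowing, out-of-plane motion, lumen blood-speckle decorrelation, and
anatomically irregular wall geometry. Passing phantom recovery therefore
demonstrates the correctness and noise behaviour of the measurement chain,
not clinical-grade accuracy on patient scans.

## Problem sizes and verification results

The test suite and the acceptance script regenerate everything from code;
the sizes below are the package's validation choices. Phantom images are
180 x 180 px at 0.2 mm/px. The reference cycle phantom runs 40 frames at
50 fps (one 0.8 s cycle); recovery ladders use 24-frame cycles at peak mean
principal strains {0.01, 0.02, 0.03, 0.05} with five seeds each and a pulse
pressure of 40 mmHg (120/80). Under those conditions the pipeline recovers
eps/PP within +-15% of the analytic value at every rung with the prescribed
rank order preserved, closes the reference cycle with drift below 10% of
peak RMS displacement, and recovers integer-pixel translations within
0.2 px. A pulseless, noise-free loop yields identically zero strain; with
the default noise level the spurious-strain floor is roughly 0.005 %/mmHg —
two to three orders of magnitude below clinically reported values, though
not zero.

## Cohort statistics

Visit pairing takes each patient's earliest visit as index and latest as
follow-up; intervals are days/365.25. Tercile cutoffs default to 0.0251 and
0.038 strain-fraction per mmHg (equivalently 2.51 and 3.8 %/mmHg), fixed
values established externally rather than quantiles of the sample at hand;
the boundary rule is closed on the intermediate interval. Published tables
in this literature print the cutoffs in mixed units; the package treats the
biomarker in %/mmHg everywhere and converts by 1/100 at the tercile
boundary, with the conversion exposed (`scale` argument) rather than baked
in. A net strain change of exactly zero classifies as "decrease" — a
documented convention, since direction must partition the cohort.

The group comparisons are deliberately nonparametric (cohorts of this size
are rarely normal, and a Shapiro-Wilk annotation is provided): tie-corrected
Kruskal-Wallis across terciles with Dunn's pairwise z tests gated on the
omnibus test, Mann-Whitney and Fisher exact tests between the
increase/decrease groups, and Spearman mid-rank correlations. For pooled
samples small enough to enumerate (n <= 9) the Kruskal-Wallis p-value is
computed exactly over all label assignments rather than by the chi-square
approximation, which is off by more than 0.03 at n = 6; the `p_method` field
reports which path ran. Dunn's tests report unadjusted and Holm-adjusted
p-values side by side, with the unadjusted column as the headline — the
clinical literature this package mirrors reports pairwise p-values without
a stated multiplicity correction, and showing both keeps that choice
visible. Table summaries use type-7 quantiles and round half away from zero
at one decimal, matching the "median [Q1, Q3]" and "k (pct)" cell formats.

## Numerical conventions and edge cases

- Strain is carried internally as a dimensionless fraction; %/mmHg appears
  only at the reporting boundary.
- The systolic and diastolic frames are identified from the strain curve
  itself (minimum and maximum, earliest frame on ties) since no intra-scan
  pressure trace exists; a constant curve warns and returns frame 0 for
  both.
- The caliper diameter is the rotating-calipers maximum over the convex
  hull of the outer contour, in cm; it equals the brute-force maximum
  pairwise distance.
- Degenerate inputs fail loudly with typed conditions: non-positive pulse
  pressure, self-intersecting or nested-incorrectly contours, inverted
  elements (named by index), nodes outside the image, zero-length groups.
- Bilinear image interpolation clamps at borders; pyramid downsampling is
  by factor 2 with a [1 2 1]/4 kernel.

## Known limitations

- Tracking operates on envelope-detected intensity, not RF data; phase
  information that some elastography systems exploit is unavailable here.
- The phantom's incompressible radial map is axisymmetric apart from the
  stiff sector; strongly eccentric deformation patterns are untested
  against analytic truth (only against the FE patch test).
- At very low true strain (~0.01) the recovered peak retains a small
  positive bias (a few percent) from residual displacement noise; estimates
  below the noise floor of ~0.002 strain-fraction should not be
  interpreted.
- The cohort layer reproduces the analysis pattern (pairing, terciles,
  rates, tests, table cells); it does not attempt survival modelling or
  multivariable adjustment.
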