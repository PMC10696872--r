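---
title: "Spinal trajectory and curvature profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spinal trajectory and curvature profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetrace)
```

## The measurement problem

Subtle spinal deformities in mice are hard to quantify from micro-CT:
classical Cobb-angle readings of 2D radiographs are insensitive to small
changes and confounded by how the animal happened to lie on the scanner
bed. spinetrace implements a biplanar annotation geometry that turns two
sets of 2D clicks into a pose-corrected, vertebra-labeled 3D trajectory,
from which a signed per-vertebra curvature profile is computed.

All computation uses a right-handed anatomical frame with x pointing
anterior (towards the nose), y left, and z dorsal; the horizontal (x–y)
plane is the top view and the sagittal (x–z) plane the side view.
Volumes are assumed reconstructed with isotropic voxels (default
0.125 mm); the world coordinate of voxel k (1-based) along an axis is
(k − 0.5) × voxel size, so voxel centers — not corners — carry the
intensities. Pixel clicks convert through the same rule
(`pixelsToMm()`).

## Pipeline

1. **Horizontal MIP** (`mip()`): each pixel is the maximum intensity
   along the dorso-ventral ray. The spinal midline is annotated here.
2. **Midline spline** (`fitMidline()`): a natural cubic interpolant
   y = f(x) through the midline points. Natural boundary conditions
   (zero second derivative at the ends) are used because they are
   parameter-free and standard; the midline must be x-monotone, which
   holds for prone animals — non-monotone annotations are rejected
   rather than re-parameterized by arc length. Evaluation outside the
   knot range clamps to the nearest endpoint value so a partial midline
   still serves the full volume.
3. **Stripe lateral MIP** (`stripeLateralMip()`): a sagittal MIP
   restricted to voxels within half a stripe width of the midline. The
   stripe suppresses ribs and limbs so the spinal canal and the ventral
   limits of intervertebral spaces stay visible from head to tail. The
   stripe width is a free parameter; the default of 1.0 mm (8 voxels at
   125 µm) is thin enough to isolate the canal in a mouse and wide
   enough to be robust to a slightly off midline. Columns whose stripe
   is empty are set to 0; only an everywhere-empty stripe is an error.
4. **Trajectory** (`buildTrajectory()`): reference points — the ventral
   limit of each intervertebral space — are clicked on the stripe image
   as (x, z); their y comes from the spline (`liftPoints()`). One
   anchor identity (e.g. L6) propagates labels to every point through
   the mouse vertebral formula Ce1–7, T1–13, L1–6, S1–4, Ca1–n
   (open-ended caudally; other species can supply their own counts).
   Each point is labeled with the vertebra immediately anterior to it,
   so consecutive points flank exactly one vertebra.
5. **Pose correction** (`correctPose()`): trajectories are centered and
   the roll (about x) and yaw (about z) rotations minimizing Σy² are
   applied. The composition Rz(yaw)Rx(roll) maps a unit direction
   m = (sin yaw, cos yaw cos roll, −cos yaw sin roll) onto the y axis,
   and m ranges over the whole sphere, so the global minimizer is
   closed-form: m is the smallest principal axis of the point scatter
   matrix. We use this eigendecomposition directly rather than
   axis-at-a-time alternation: alternation has the same fixed points
   when it works, but for lateral tilts beyond a few degrees its roll
   step can swallow the yaw-induced lateral spread by rolling toward
   90°, leaving it stuck in a poor local minimum. The estimate is still
   iterated (tolerance 1e−8 rad, cap 50); the second sweep is the
   identity up to round-off. Note an intrinsic property, shared by any
   corrector of this form: when roll and yaw are both nonzero, the
   corrective angles are not the negatives of the applied ones (Rx and
   Rz do not commute); what is recovered exactly is the sagittal plane.
   A trajectory collinear with the x axis leaves roll/yaw undetermined
   and returns the identity pose with a warning.
6. **Cohort alignment** (`alignCohort()`): iteratively, the per-label
   average position is computed and each trajectory is translated
   within the sagittal plane to minimize the summed squared distance of
   its points to the per-label averages, using a grid search (coarse
   ±5 mm at 0.25 mm, then fine ±0.25 mm at 0.01 mm around the coarse
   optimum; the quadratic objective is evaluated in closed form on the
   grid). Ties break toward the smallest-magnitude translation, then
   lexicographically, for determinism. Convergence is declared when the
   largest applied translation falls below 1 µm. Matching is by
   vertebral label, not ordinal index — the only identity-safe choice
   when scans cover the spine variably — and only labels present in at
   least two trajectories participate. The objective is verified
   non-increasing at run time (each grid step cannot worsen its own
   term because the zero translation is on the grid, and re-averaging
   can only decrease the total).
7. **Curvature** (`curvatureProfile()`): each flanked vertebra gets an
   anterior-pointing unit axis from its flanking reference points; the
   local curvature at vertebra i is the angle between the axes of its
   posterior and anterior neighbors, computed as
   atan2(‖v⁻ × v⁺‖, v⁻·v⁺) and reported in degrees. For acute angles
   this equals the arcsine of the cross-product norm; atan2 remains
   correct past 90°. The sign is taken from the y component of
   v⁻ × v⁺, which makes dorsally convex (kyphotic) sagittal bends
   positive in this frame. The convexity sign rule is a convention, not
   a measurement; `flipSign = TRUE` selects the opposite one. Profiles
   are invariant under rigid motions, so centering, pose correction and
   alignment cannot change them. `groupProfiles()` summarizes cohorts
   as mean, sample SD and n per vertebral level; per-animal tables
   (`writeCurvatureCSV()`) are the hand-off to external statistics
   (mixed-effects modeling is deliberately out of scope).

## Ventricle volumetry

`sliceArea()` counts supra-threshold ("white patch") pixels per T2 MR
slice, optionally within an ROI, times the pixel area;
`seriesVolume()` multiplies the summed area by the slice thickness
(default 0.6 mm, the acquisition thickness this rule is designed for);
`meanSliceArea()` averages cross-sections (used for overall brain
size). The original measurements were manual segmentations; this module
reproduces the arithmetic over either pre-drawn masks or a global
threshold plus ROI and does not claim to replicate manual judgment —
the greyscale cut-off is an explicit input, never inferred.

## The phantom generator

`phantomSpec()` / `makePhantomTrajectory()` create ground-truthed
synthetic spines. Reference points are placed at equal arc-length steps
along a parametric curve; the defaults are chosen to resemble the real
cohorts: 26 points at 2.5 mm spacing (vertebra-scale spacing in adult
mice, covering T4..Ca6 with the L6 anchor at point 11), one dorsal
Gaussian bump of amplitude 4 mm and SD 10 mm over the thoracic band
(the natural thoracic kyphosis), zero lateral deviation, point jitter
SD 0.1 mm (annotation-click precision at 125 µm voxels), and a
configurable roll/yaw/offset pose. A circular-arc profile is sampled
analytically so the closed-form chord result (constant angle 2s/R for
arc spacing s and radius R) holds to machine precision.
`voxelizePhantom()` renders chord-oriented ellipsoidal vertebral bodies
(semi-axes 0.9 × 0.6 × 0.6 mm, leaving visible intervertebral gaps at
2.5 mm spacing) over constant background with optional Gaussian noise.
All randomness flows from the single spec seed (the voxel-noise stream
derives from it); the caller's RNG state is saved and restored.

Ground truth (labels, pose, per-vertebra curvature) is computed from
the noiseless, pose-free points, and truth curvature uses an
arccos-of-dot evaluation kept separate from the production atan2 code
path, so the system under test never grades itself. End-to-end tests
annotate at the true landmark projections (`autoAnnotate()`) rather
than detecting landmarks in images — landmark detection is explicitly a
non-goal.

What the phantom does not emulate: CT physics (beam hardening,
scatter), soft tissue and ribs, partial scan coverage gradients, or any
systematic annotation bias. Passing tests therefore demonstrate the
geometry and numerics of the pipeline, not robustness to real-scan
image quality.

## Error propagation and validation scales

Annotation jitter maps to curvature noise as roughly 2σ/s radians per
vertebra (σ = point jitter SD, s = reference-point spacing): two
endpoints per axis and two axes per angle each contribute √2. At
σ = 0.1 mm and s = 2.5 mm that is ≈ 4.6° SD, i.e. a mean absolute error
near 3.7° for a single animal. Per-animal profiles at this noise level
are therefore dominated by annotation noise, and the meaningful
quantity is the cohort-averaged profile, whose error shrinks by √n
(≈ 1.3° expected at n = 12). The test suite checks exactly that: a
noiseless phantom must reproduce truth within 0.1° per vertebra, and
the 12-animal jittered cohort mean within 2° MAE.

Validation problem sizes were chosen to keep the whole suite fast while
exercising every path at realistic scale: oracle cross-checks run on
100 small random volumes (stripe projection), 10⁶ random acute
unit-vector pairs (angle formulas), and 20 random knot sets (spline vs
an independently coded tridiagonal solver); the alignment convergence
check uses the full 12-animal, 26-point cohort with ±3 mm random
sagittal offsets; voxelized end-to-end recovery uses one full-size
volume at 125 µm.

## Known limitations

* The spline parameterization y = f(x) assumes an x-monotone midline;
  severely rotated or coiled postures would need arc-length
  parameterization, which is out of scope.
* Only roll and yaw are corrected and only sagittal translations are
  aligned, mirroring the measurement design; pitch errors and
  antero-posterior scaling are not modeled.
* The trajectory container enforces the label structure (consecutive
  vertebral ordinals) as a hard invariant but not x-monotonicity, since
  legitimate rigid motions (e.g. a strongly curved arc under rotation)
  can break it; x-monotonicity is enforced where it is an actual
  assumption, at annotation/construction time.
* Curvature at the first and last flanked vertebrae is undefined (no
  neighbor axis); n reference points yield n − 3 angles.
* The convexity sign convention relative to the anatomical frame is a
  documented choice (`flipSign` to invert).
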