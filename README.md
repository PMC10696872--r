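# spinetrace

Quantitative spine morphometry for small rodents from micro-CT, for
researchers characterizing skeletal phenotypes (scoliosis/kyphosis
models, mutants with subtle spinal geometry changes) where classical
Cobb-angle readings of 2D radiographs are too coarse and confounded by
animal placement.

## What it computes

Working in a right-handed anatomical frame (x anterior, y left,
z dorsal), the pipeline turns two sets of 2D annotations into a
pose-corrected, vertebra-labeled 3D spinal trajectory and a signed
curvature profile:

* **Projections.** A horizontal maximum intensity projection (MIP) for
  midline annotation, and a *stripe* lateral MIP restricted to voxels
  within ±w/2 of the spinal midline (default w = 1 mm), which keeps the
  spinal canal and intervertebral spaces visible.
* **Midline spline.** A natural cubic interpolant y = f(x) through the
  horizontal-plane midline points.
* **Trajectory.** Reference points — the ventral limit of each
  intervertebral space — annotated as (x, z) on the stripe image are
  lifted to 3D via y = f(x) and labeled from one anchor vertebra
  through the mouse vertebral formula (Ce1–7, T1–13, L1–6, S1–4,
  Ca1–n); each point is named for the vertebra immediately anterior.
* **Pose correction.** The roll and yaw rotations minimizing Σy²
  (closed form: the scatter matrix's smallest principal axis is mapped
  to y), removing bed-placement tilt.
* **Cohort alignment.** Iterative sagittal-plane translations toward
  the evolving per-label average, each found by a coarse/fine grid
  search; converges when the largest applied translation is below 1 µm.
* **Curvature.** Vertebra i gets a unit longitudinal axis **v**ᵢ from
  its flanking reference points; local curvature is the signed angle
  between **v**ᵢ₋₁ and **v**ᵢ₊₁,
  θᵢ = atan2(‖**v**ᵢ₋₁ × **v**ᵢ₊₁‖, **v**ᵢ₋₁·**v**ᵢ₊₁)
  (equal to arcsin ‖**v**ᵢ₋₁ × **v**ᵢ₊₁‖ for acute angles), with
  dorsal convexities (kyphosis) positive. Group profiles report
  mean ± SD per vertebral level.
* **Ventricle volumetry.** Thresholded bright-patch areas per T2 MR
  slice; volume = total area × slice thickness (default 0.6 mm).
* **Phantom generator.** Ground-truthed synthetic spines (known
  profile, pose, jitter, voxelized volumes) so every stage is testable
  without a scan.

See `vignettes/spine-curvature-profiling.Rmd` for the methods account.

## Worked example

```r
library(spinetrace)

# a synthetic animal: thoracic kyphosis, tilted 6 deg roll / -4 deg yaw
spec <- phantomSpec(seed = 7, pose = list(roll = 6*pi/180, yaw = -4*pi/180,
                                          dx = 1.5, dz = -0.8))
ph <- makePhantomTrajectory(spec, subject = list(animal = "m01"))
ph$trajectory
#> SpineTrajectory: 26 reference points (Ca6 .. T4)
#>   subject: animal=m01

res <- correctPose(ph$trajectory)
res$pose
#> PoseParameters: roll -5.6483 deg, yaw 3.9851 deg (2 iterations, converged)

prof <- curvatureProfile(res$trajectory)
round(angles(prof)[c("T10", "T9", "T8", "T7")], 2)
#>   T10    T9    T8    T7
#>  7.99 14.05  9.80  2.63
```

The corrective pose is close to minus the applied tilt (they differ
slightly because roll and yaw do not commute; the sagittal plane itself
is restored exactly). Mid-thoracic angles are positive — the dorsally
convex kyphosis — and deviate from the noiseless truth by a few degrees
because of the default 0.1 mm annotation jitter; averaging a cohort
recovers the profile:

```r
cohort <- lapply(1:12, function(i)
  makePhantomTrajectory(phantomSpec(seed = i))$trajectory)
set.seed(1)
cohort <- lapply(cohort, function(tr)
  applyPose(tr, dx = runif(1, -3, 3), dz = runif(1, -3, 3)))
al <- alignCohort(cohort)
al
#> CohortAlignment: 12 trajectories, 4 iterations, objective 7.49179 mm^2

gp <- groupProfiles(lapply(alignedTrajectories(al), curvatureProfile))
subset(gp, vertebra %in% c("T10", "T9", "T8"))
#>   group vertebra ordinal mean_deg sd_deg  n
#>     all      T10      17     11.5   4.63 12
#>     all       T9      16     11.6   2.49 12
#>     all       T8      15     10.1   3.58 12
```

Per-vertebra SD (~3–5°) is the expected annotation-noise level at
0.1 mm jitter and 2.5 mm spacing; the n = 12 mean is accurate to ~1°.
Volumetry is plain slice arithmetic:

```r
seriesVolume(c(12.4, 15.1, 9.8))   # areas in mm^2, 0.6 mm slices
#> [1] 22.38
```

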