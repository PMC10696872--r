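Package: spinetrace
Title: Three-Dimensional Spinal Trajectory and Curvature Profiling for
    Rodent Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative spine morphometry in small rodents from
    micro-CT volumes. Computes maximum intensity projections (including a
    stripe-restricted lateral projection that follows the spinal midline),
    fits a cubic-spline midline from horizontal-plane annotations, lifts
    lateral-plane intervertebral reference points to labeled
    three-dimensional spinal trajectories, corrects animal pose (roll and
    yaw minimizing lateral spread), aligns cohorts of trajectories by
    iterative sagittal grid-search translation, and derives signed
    per-vertebra curvature profiles with group summaries. Also implements
    slice-based ventricle volumetry (thresholded area times slice
    thickness) for T2 MRI series, and a ground-truthed synthetic spine
    phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'vertebrae.R'
    'trajectory.R'
    'alignment.R'
    'annotations-io.R'
    'curvature.R'
    'midline.R'
    'phantom.R'
    'projections.R'
    'spinetrace-package.R'
    'volume-io.R'
    'volumetry.R'
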