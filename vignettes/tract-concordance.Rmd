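---
title: "Validating tract localization against serial-section reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tract localization against serial-section reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Probabilistic tractography infers white-matter pathways from diffusion
orientation estimates, and its output is routinely used to target small,
clinically relevant bundles such as the dentatorubrothalamic tract (DRTT) --
the cerebellar output pathway that leaves the dentate nucleus, decussates in
the mesencephalon and terminates in the contralateral thalamus. Whether a
thresholded connectivity map actually coincides with the anatomical tract can
only be established against an independent reference, classically a
histological segmentation of the same specimen reconstructed into 3D.
That validation pipeline has three fragile links: the tracking itself
(dispersion, crossing fibers, curvature gating), the 3D reconstruction of
deformed serial sections (which must not straighten curved anatomy), and the
voxel-wise concordance analysis (whose specificity depends on the evaluation
region). `tractconcord` implements all three links as testable components and
exercises them end to end on synthetic phantoms with known ground truth, so
that every stage's failure modes can be measured rather than assumed.

## The phantom world

`build_phantom()` constructs a mirror-symmetric pair of tubular tracts from
natural cubic splines through five control points per side. Each centerline
starts in an ipsilateral "dentate" blob low in the volume, crosses the
midline exactly once at mid-height, and ends in the contralateral "thalamus"
blob. The tract mask is the set of voxels within `tube_radius_mm` of the
centerline; seed and target masks are end caps of the tract (first/last 6% of
arc length), so they are subsets of the tract support by construction. A
one-voxel midsagittal slab strictly below the decussation serves as the
exclusion mask, mirroring the practice of blocking midline crossing below the
level of the decussation.

Fiber orientations follow the local centerline tangent. Within the crossing
zone (voxels within `crossing_zone_extent_mm/2` of the midsagittal plane)
every tract voxel carries two populations -- its own tangent and the mirrored
tangent of the twin tract -- with volume fractions 0.5/0.35 (0.45/0.45 where
the two tubes physically overlap). Orientation dispersion is Watson-type
(axial, antipodally symmetric) with concentration `dispersion_kappa`
(default 60, a scatter of roughly 5 degrees about the axis; values above 1e5
are treated as dispersion-free). The intensity volume -- the stand-in for
block-face/structural contrast -- is a bright tube over a dim background plus
30 smooth random texture bumps. The bumps matter: they give the Harris
landmark detector corners to find and the intensity-based registration a
signal away from the tract.

Defaults: 48^3 voxels at 0.5 mm (a 24 mm field of view around the
brainstem/cerebellum region of interest). All randomness derives from one
seed through named substreams, so phantoms are bit-reproducible.

What the generator does *not* emulate: MR contrast physics, staining
variability, cortical artefacts, realistic folia, or fitted (noisy) fiber
orientation posteriors. A green test therefore establishes that the
*machinery* is correct under the stated noise model, not that any particular
in-vivo protocol would achieve the same concordance.

## Tractography semantics

`run_tractography()` launches `samples_per_seed_voxel` (default 2000)
streamlines from uniformly jittered positions in every seed voxel, stepping
0.5 mm. At each step one fiber population of the containing voxel is sampled
with probability proportional to its volume fraction -- populations below
`fraction_floor` (default 0.05) are excluded, the deterministic analog of
automatic relevance determination pruning -- and a direction is drawn from
the Watson distribution about its axis, sign-aligned with the previous
direction. A draw whose cosine with the previous direction falls below the
curvature threshold (default 0.2, i.e. a maximal turn of ~78 degrees)
terminates that branch without rejecting the streamline. Entering the
exclusion mask rejects the whole streamline; reaching the target terminates
and accepts it. Propagation is bidirectional with the two half-tracks merged;
field lookup is nearest-voxel, because interpolating axial orientations is
ill-defined.

Accepted streamlines increment each visited voxel at most once (a visit set,
not a visit count), so the normalized map is interpretable as a per-streamline
visitation probability bounded by 1. Normalization divides by the number of
streamlines "generated between the seed and target mask", which we read as
the accepted count; since the alternative (attempts) only rescales thresholds
by the acceptance rate, it is exposed as `normalize_by = "attempted"`.

The Watson sampler uses rejection from the uniform sphere with acceptance
`exp(kappa((mu.x)^2 - 1))`; at kappa = 60 roughly one draw in nine is
accepted, which is why the propagation core is compiled.

## Sectioning, deformation and reconstruction

`simulate_sectioning()` samples planes perpendicular to the third axis at
spacing thickness x retention interval (the default run configuration uses
10 um sections with every 20th retained, i.e. 200 um inter-plane spacing) and
keeps undeformed copies as block faces. `deform_stack()` warps each slice by
a Gaussian-smoothed white-noise displacement field scaled to a maximum of
`amplitude_mm`, composed with a small random affine whose magnitude also
scales with the amplitude; fields are rejection-sampled until the discrete
Jacobian determinant exceeds 0.1 everywhere, so the stored ground-truth warp
is invertible and recovery tests are meaningful. Landmarks (at least six per
slice, Harris corners with enforced mutual separation) are carried through
the warp by fixed-point inversion, so each pair satisfies dst = warp(src) to
1e-6 by construction.

The deformation defaults are a deliberate choice the literature does not fix:
real histological deformations are reported only qualitatively. We use
amplitude 2 mm with smoothness 5 mm. At this package's 24 mm field of view a
10 mm characteristic length produces a warp that a 6-DOF affine fit absorbs
almost entirely (landmark-affine residual ~0.03 mm), leaving the nonlinear
stage nothing to demonstrate; 5 mm -- about one fifth of the slice extent --
yields the spatially variable, locally varying distortion the nonlinear stage
exists to correct.

Reconstruction proceeds in the order used for real material: per-slice
landmark affine to the block face (`initial_reconstruct()`), then iterative
multivariate nonlinear refinement (`refine_nonlinear()`). Each iteration
computes, per slice, a demons-style displacement update against a weighted
combination of the corresponding reference-volume slice (weight 0.5) and the
two neighbouring slices at their current estimates (0.25 each, Gauss-Seidel
order for determinism and faster consistency propagation; boundary slices
renormalize over the available neighbors). Updates are smoothed with a
Gaussian of `smoothing_sigma_mm` (default 2 mm) and composed onto the running
field; the loop stops after `n_iterations` (default 20) or when the mean
update falls below `convergence_tol` (0.01 mm). Sum-of-squared-difference is
used as the cost: the synthetic slices share contrast with the reference, so
mutual information machinery would add nothing here; the cost sits behind a
single function so it can be swapped.

Two numerical choices deserve a note. The divergence guard aborts when the
cost exceeds 1.01 x the best value seen for three consecutive iterations: the
demons equilibrium between the reference term (pulling toward truth) and the
neighbor terms (pulling toward inter-slice similarity) jitters by well under
1%, and a literal "any increase" rule would abort healthy runs. The curvature
statistic used for the banana-problem check is the mean distance of the 3D
curve of per-slice bright-structure centroids (x, y, slice position) from its
total-least-squares line; an end-to-end chord is degenerate for symmetric
arcs. With the reference weight at its default the curvature ratio of a
curved tube stays within 10% of truth; setting it to zero reproduces the
classical straightening artefact (ratio ~0.2 on the demonstration fixture),
which is exactly why block-face/reference anchoring is part of the protocol.

## Concordance analysis

`roc_and_si_curves()` sweeps connectivity thresholds (default: 100 evenly
spaced values over 0-0.35% of total streamlines), computing confusion counts,
TPR = TP/(TP+FN), FPR = FP/(FP+TN) and the Dice similarity index
SI = 2|A∩B|/(|A|+|B|) over a stated analysis ROI. Restricting the evaluation
region is the default because the number of true negatives -- and hence the
specificity -- otherwise depends on how much empty volume the masks happen to
share; the ROIs used by the pipeline are padded bounding boxes around the
dentate, peduncle and decussation zones (the zones themselves contain no
reference-negative voxels, so rates would be undefined on them). The whole
decussation is used as reference for both left and right evaluations, because
the mingling of the two bundles there makes separate segmentation
meaningless; this inflates false negatives in the decussation by design.

AUC is the trapezoid over (FPR, TPR) sorted by FPR with (0,0) and (1,1)
anchors -- with one threshold per distinct map value this equals the rank
statistic with ties counted half, which is what the test-suite oracle checks
exhaustively. The optimal threshold is the smallest threshold attaining the
maximal SI (the more sensitive mask is preferred at ties). Degenerate
denominators raise typed conditions rather than propagating NaN. Dice over
two empty masks is defined as 0, not 1, so degenerate predictions are never
rewarded. The false-negative dilation profile grows the thresholded mask by
one voxel at a time with the 6-connected (face) structuring element -- the
most conservative reading of "steps of one voxel" -- and reports the covered
fraction of the reference at each margin in mm (requires isotropic voxels).
Rater averaging (`average_reports()`) takes arithmetic means of rates and
summary statistics per (ROI, threshold) cell and sums counts for reference.

## Reproducibility and I/O

A master seed fans out to per-stage substreams through a stable name hash,
so adding a stage never perturbs earlier draws and two runs of
`run_pipeline()` with equal configuration produce byte-identical reports.
Volumes travel as NIfTI-1 with voxel size in the header (a minimal
uncompressed little-endian codec is bundled, as no NIfTI package is available
in the target environment; the test suite cross-checks the files against
nibabel). Landmarks and report curves are CSV; configurations are YAML;
summaries and the manifest are JSON; plots are SVG when a cairo device is
available.

## Known limitations

* Acceptance rates on the crossing phantom are low (a few percent): in the
  two-population zone the twin bundle's near-orthogonal axis is sampled in
  proportion to its volume fraction, and such a draw terminates the branch at
  the curvature gate, so most streamlines die in the decussation. The
  accepted set is clean -- which is what the crossing-fidelity property
  measures -- but absolute counts per seed are small, so the practically
  useful part of the 0-0.35% threshold sweep begins only once thousands of
  streamlines are accepted.
* The demons refinement assumes shared contrast between slices and reference;
  real stained sections would need the mutual-information cost stub filled
  in, plus the 12-DOF volume registration that the synthetic world replaces
  with an exact frame correspondence.
* Landmark error is evaluated at the same landmarks used for the affine fit
  (as an investigator would), so the affine-only error understates true
  misalignment away from landmarks; the intensity RMS metric covers the rest
  of the slice.
* The deformation model is elastic-smooth and fold-free; tears, folds and
  missing tissue -- all observed in real sectioning -- are out of scope.
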