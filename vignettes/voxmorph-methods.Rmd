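---
title: "Methods: 3D reconstruction, morphometry and the density-criterion fragmentation measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D reconstruction, morphometry and the density-criterion fragmentation measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `voxmorph`, in the spirit of a methods section: what is
computed, under which assumptions, and where the genuinely open design
decisions were made.

## Input model

The package assumes confocal z-stacks of suspended, triple-stained cells:
red = nuclear stain, green = mitochondrial stain, blue = membrane-bound
apoptosis marker (Annexin V). Frames are 12-bit per channel (intensities in
0–4095, hard ceiling at 4095), with square xy pixels (`pixel_size_xy`, µm)
and a nominal stage step in air (`z_step_air`, µm) between slices. Channel
identity is positional (red, green, blue page samples) unless remapped by
the caller; stacks travel as multi-page TIFF with a JSON sidecar because no
single vendor-native format can be assumed.

## Segmentation

Per-slice thresholds come from Otsu's between-class-variance maximization on
the ROI histogram, evaluated at the full 4096-level resolution. Otsu was
chosen because it is deterministic and parameter-free; "histogram analysis"
admits many readings and reproducibility was the deciding criterion.

A red or green slice is split three ways (background / cytoplasm / bright
organelle) using two cuts. On a frame that contains background, cytoplasm
and a bright organelle, the maximal between-class variance falls at the
strongest gap — typically between cytoplasm and the organelle — so
`segment_slice()` treats the supplied threshold as the *upper* (organelle)
cut and recovers the cell/background cut by a second Otsu pass restricted to
the sub-threshold pixels. Each candidate cut is accepted only if the two
classes it separates differ by at least `min_contrast` intensity units in
mean (default 50, roughly 3 SD of typical detector noise on this intensity
scale); otherwise the structure is deemed absent and the scheme degrades
gracefully: slices without a bright organelle yield cytoplasm only, slices
without cytoplasm yield organelle only, and noise-only or constant slices
yield all-background maps. This guard is what prevents empty slices from
being welded into spurious objects by the morphological cleanup.

Cleanup uses a 3×3 closing, hole filling, and removal of components below
`min_component_px` (cell masks, default 20 px) or `min_organelle_px`
(organelles, default 5 px — smaller because mitochondrial cross-sections can
be only a few pixels). Touching nuclei are separated by a watershed on the
distance transform. All element sizes are defaults exposed in the
configuration; none are claimed to be canonical.

The membrane is a geometric shell of `shell_px` (default 2) pixels on each
side of the fused cell-mask boundary, eroded/dilated with a disc element and
with explicit background padding so a mask touching the frame edge still has
a shell there. An optional intensity cut at a blue-channel threshold exists
but is off by default: viable cells carry no Annexin V signal, and an
intensity cut computed on a blank channel would empty their membrane set and
make viability undetermined. The blue signal instead enters at
classification time (below), which keeps the geometric shell well-defined
for every cell.

## Reconstruction

The red- and green-derived cell outlines of each slice are fused by keeping
whichever has the larger pixel count (ties to red). The true inter-slice
distance is `0.87 × z_step_air` (refraction correction for an aqueous sample
imaged through the nominal air step; the factor is configurable). To
approach cubic voxels, `m = round(dz_true/dx) − 1` planes are interpolated
between each acquired pair: intensities linearly, labels copied from the
nearest acquired plane (ties toward the lower plane) because labels are
categorical and interpolation would invent sub-voxel boundaries. Label
priority per plane is cytoplasm < membrane < mitochondrion < nucleus, and
the membrane label is restricted to the part of the shell inside the cell
mask so the labelled cell volume is not inflated by an outer ring.

Cells are 26-connected components of non-background voxels (6-connectivity
is used only for face-exposure tests); components touching any lattice
boundary are flagged truncated. Physical coordinates are voxel centers,
`x = (i + 0.5)·dx`, 0-based indices.

Viability: a cell is apoptotic iff the mean blue intensity over its membrane
voxels exceeds the off-cell background mean by more than `k_sd` background
SDs (default 3 — the comparison against background is given by the assay
logic, the 3-SD margin is this package's choice of a conventional
significance margin). An empty membrane set yields "undetermined" rather
than a guess.

## Morphometry conventions

All quantities are voxel-counting based, which keeps them exactly
reproducible on a given lattice:

* `V` = voxel count × voxel volume; `S` = exposed-face count × face area
  (per-axis areas, so anisotropic voxels are handled); `GP` = boundary-voxel
  count × xy pixel size.
* Face counting inflates smooth surfaces by a factor approaching 3/2: a
  digital ball has S → 6πr², hence VSi = 4πER²/S → 2/3 and SVr·ER → 4.5.
  These limits, not 1 and 3, are the correct reference values for round
  objects under this convention, and the test suite asserts them on digital
  balls.
* Centroids are unweighted voxel-center means; membrane-to-centroid
  statistics use the population SD (the membrane voxels are the full
  population of the object, not a sample).
* Mitochondria are measured as the union of all mitochondrial voxels; no
  per-instance morphometry is attempted.

The inflection-point count `N_si` has no grid-standard definition, so the
package defines it explicitly: per acquired slice, the outer contour of the
cell mask is extracted, resampled to arc-length-equidistant points about 4 px
apart (this removes pixelation staircases at every scale), coordinates and
the curvature signal are each smoothed with the five-point cubic window, and
sign changes of the smoothed curvature are counted with a dead band of 20%
of the curvature of a circle with the same perimeter (so a digital circle of
any radius counts 0, while an n-lobed contour counts 2n). `N_si` is the sum
over acquired slices. Absolute values are comparable only within this
definition; between-group *differences* are the meaningful signal.

## The fragmentation measure

The nuclear red-channel histogram (bin width 1 over 0–4095) is smoothed with
a cubic Savitzky–Golay fit over a five-point window. The threshold is

* `I_th = (I_m + I_5%)/2`, with `I_m` the smoothed mode and `I_5%` the first
  intensity above `I_m` at which the smoothed count is ≤ 5% of its maximum
  (the scan runs upward only — the saturation clause implies that
  direction);
* `I_th = (I_m + 4095)/2`, flagged saturated, when no such intensity exists
  below the 12-bit ceiling;
* for a single-occupied-bin histogram, `I_th` equals that intensity (all
  voxels valid) — the midpoint rule applied to a five-point smoothed spike
  would otherwise exclude every voxel.

Valid voxels (`I ≥ I_th`) are clustered by recursive division. For a
cluster, ρ is its member count divided by the number of *geometric* lattice
sites (the infinite grid at the lattice spacing, not clipped to nucleus or
stack — no clipping is part of the definition) whose centers fall in the
closed sphere centred at the centroid with radius to the furthest member; a
singleton has ρ = 1 by convention. A tentative 2-means split is accepted iff
the daughters' mean density is ≥ `density_gain` (default 1.5) × the parent
density, with "≥" kept at exact equality as stated. Termination is
guaranteed: ρ ≤ 1 and each accepted split multiplies density by ≥ 1.5, so
any cluster with ρ > 2/3 is a leaf and the recursion depth is bounded by
log₁.₅(1/ρ_root) + 1.

Two implementation details are deliberately non-standard and matter in
practice:

1. **Candidate selection.** Candidate bipartitions are 10 random-initialized
   Lloyd runs (deterministic sub-seeds derived from the user seed and the
   node's tree path), one run initialized at the two mutually furthest
   members, and — when the valid set has several 26-connected components — a
   grouping of whole components by 2-means on their centroids. Among the
   candidates, the one with the largest mean daughter density is tested
   against the acceptance inequality. Selection by within-cluster sum of
   squares instead is provably pathological here: k-means prefers bisecting
   a compact fragment over isolating a single stray voxel, and once a stray
   exists the acceptance inequality happily ratifies the cascade,
   systematically overcounting fragments. Scoring candidates by the
   method's own density objective removes the pathology without touching
   the acceptance rule.
2. **Minimum leaf size.** `N_cl` counts leaves holding at least
   `min_leaf_frac` (default 1%) of the valid voxels. Stray voxels cut off a
   fragment boundary by a k-means plane then do not masquerade as
   fragments; all leaves, including tiny ones, remain reported.

## The phantom generator

Phantoms emulate what the pipeline consumes: ellipsoidal cells with diffuse
red cytoplasm signal, a spherical nuclear envelope, optional bright nuclear
fragments, scattered mitochondrial blobs, an optional blue membrane band
just inside the cell surface, Gaussian (default SD 15, ≈ 3% of the
cytoplasm–background contrast) and optional Poisson noise, and hard clipping
at 4095. Geometry is sampled at the *true* plane spacing
`0.87 × z_step_air` while the metadata records the air step, so the
pipeline's refraction correction recovers physical volumes — this mirrors
real acquisition, where the nominal stage step overstates the in-sample
spacing.

Two rendering choices deserve explanation. Intact nuclei are uniformly
bright, while fragmented nuclei get a *dim envelope with a rim-weighted
gradient* and fragments rendered *into 12-bit saturation* with per-fragment
intensity variation. The saturation choice exercises the threshold rule's
saturation branch and reflects the imaging reality that condensed chromatin
is locally much brighter than the degraded surroundings; it also makes the
valid set essentially identical to the true fragment mask. For an
unsaturated unimodal envelope the midpoint rule intrinsically marks the
brightest ≈ 11% of envelope voxels valid (the rule is location–scale
invariant on a Gaussian), which is a property of the method, not a bug, and
is why purely sub-saturation fragment phantoms cannot achieve near-perfect
valid/fragment agreement.

What the phantoms deliberately do not model: the optical point-spread
function, spectral bleed-through, depth-dependent attenuation, and
non-spherical nuclei. Passing the phantom suite therefore demonstrates the
correctness of the discrete pipeline — thresholds, reconstruction
arithmetic, voxel measures, the clustering criterion — not robustness to
every optical artifact of real stacks.

## Group statistics

Two-tailed Welch (unequal-variance) t-tests per parameter, computable from
summaries (mean, SD, n) alone; the Welch form was adopted because
recomputation from the bundled cohort summary table matches its printed
p-values closely. No multiple-testing correction is applied, matching the
reference analysis; the significance flag is exactly p ≤ 0.05. The bundled
table ships verbatim, including one mitochondrial grid-perimeter row whose
printed summaries and p-value are mutually inconsistent under any t-test
variant and one volume-ratio row printed with too few digits to pin its
p-value down; both are marked in the table's `consistent` column and
excluded from reproduction checks, with the inconsistency itself asserted
in the test suite.

For calibration studies the cohort sampler draws each parameter
independently normal from the reference means and SDs. That is sufficient
for the type-I error of per-parameter tests (each column is marginally
calibrated) but deliberately ignores inter-parameter correlations, so it
must not be used to study joint error rates across parameters.

## Problem sizes used in the checks

The automated checks run on sizes chosen to make each property decisive at
small cost: digital balls of radius 8–10 voxels for the face-counting
limits, 32³ lattices with up to 80-voxel clusters for the exact density
oracle, 200 dense clusters for the no-split law, 50 clustering seeds per
fragment count for recovery, a 96×128×30 six-cell stack for the end-to-end
viability check, and 200 replicate cohort pairs of 50 cells for the type-I
calibration.

## Known limitations

* Segmentation assumes the organelle is the brightest compartment of its
  channel and at least `min_contrast` above the cytoplasm; weakly stained
  nuclei will merge into cytoplasm rather than be guessed.
* A slice of constant intensity is indistinguishable from background and is
  treated as empty.
* `N_si` is definition-bound (above); comparisons across software are not
  meaningful.
* The fragmentation measure inherits the threshold rule's ≈ 11% bright-tail
  behaviour on broad unimodal nuclei: the valid set of an intact nucleus is
  a sparse scatter, whose division the density criterion rejects, giving
  N_cl = 1 — but the valid set itself should not be interpreted as a
  chromatin mask in that regime.
* Cells touching the stack boundary are flagged, not repaired; their
  morphometry is biased and should be filtered on the `truncated` column.
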