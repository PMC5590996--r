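# voxmorph

Voxel-based 3D morphometry and nuclear fragmentation analysis of
multi-channel confocal image stacks.

## The problem

Apoptotic cells change shape in characteristic ways — the cytoplasmic and
nuclear surfaces roughen, mitochondria condense, and in later stages the
nucleus breaks into discrete chromatin bodies. Quantifying these changes in
3D requires reconstructing individual cells from confocal z-stacks of
triple-stained suspensions (a nuclear stain such as Syto-61 in the red
channel, a mitochondrial stain such as Mito-Tracker Orange in green, and
membrane-bound Annexin V in blue) and measuring organelle morphology on the
resulting voxel grids. `voxmorph` implements that workflow for 512×512-class
12-bit stacks, plus a synthetic phantom generator with analytic ground truth
so that every stage can be validated without microscope data.

## What it computes

**Reconstruction.** Each slice of the red and green channels is thresholded
by Otsu's between-class-variance criterion on the ROI histogram and
segmented into background / cytoplasm / organelle with morphological
cleanup and a watershed split of touching nuclei. The two channels' cell
outlines are fused (larger area wins), the z spacing is corrected for
refraction (true spacing = 0.87 × air step), and extra slices are linearly
interpolated so that voxels become as cubic as possible. Cells are the
26-connected components of the labelled lattice; a cell is called apoptotic
when its membrane-shell voxels average more than 3 background SDs of
Annexin V fluorescence.

**Morphometry.** For each cell, 28 morphology parameters and 4 fluorescence
parameters: per organelle o ∈ {cell c, nucleus n, mitochondria m} the grid
perimeter GP_o (boundary-voxel count × pixel size), face-counted surface
area S_o, volume V_o, surface-to-volume ratio SVr_o = S/V, surface
irregularity index SIi_o = GP/√V, equivalent radius ER_o = (3V/4π)^(1/3),
volume sphericity index VSi_o = 4πER²/S, membrane-to-centroid distance
statistics ⟨R_o⟩ and ΔR_o, the nucleus-to-cell centroid distance CD_nc,
volume ratios Vr_nc and Vr_mc, an inflection-point count N_si from the
smoothed contour curvature, and the mean/SD of nuclear and mitochondrial
fluorescence. With face counting a digital ball has S → 6πr², so VSi → 2/3
rather than 1 for perfectly spherical objects; the ~0.66–0.68 values typical
of round cells reflect that grid-based convention.

**Nuclear fragmentation.** The red-channel intensities of the nuclear
voxels are compiled into a unit-bin histogram, smoothed with a five-point
cubic (Savitzky–Golay) window, and thresholded at
I_th = (I_m + I_5%)/2, where I_m is the histogram mode and I_5% the first
intensity at which the smoothed count falls to 5% of its maximum — or
I_th = (I_m + 4095)/2 when the count stays above 5% up to 12-bit
saturation. Voxels at or above I_th are "valid". Valid voxels are divided
by recursive 2-means clustering: a tentative split into daughters with
densities ρ₂₁, ρ₂₂ (density = valid voxels / lattice sites inside the
centroid-centred sphere reaching the furthest member) is kept iff

    (ρ₂₁ + ρ₂₂) / 2 ≥ 1.5 · ρ₁₁

against the parent density ρ₁₁. The final leaf count N_cl is the
fragmentation measure: an intact nucleus gives N_cl = 1, a fragmented one
N_cl ≥ 2. Since ρ ≤ 1, any cluster denser than 2/3 can never be split.

**Group statistics.** Viable and apoptotic cohorts are compared per
parameter with two-tailed Welch t-tests (computable from raw tables or from
mean/SD/n summaries); parameters with p ≤ 0.05 are flagged. A bundled
reference table of cohort summaries for 101 viable and 105 apoptotic MCF-7
cells allows cross-checking the machinery against published p-values.

## Worked example

A single apoptotic phantom cell (radius 7 µm, nucleus 5 µm) whose nucleus
holds three condensed chromatin fragments rendered into 12-bit saturation,
imaged at 0.35 µm pixels with a 0.4 µm air z-step:

```r
library(voxmorph)

nc <- c(12.6, 12.6, 7)
frags <- lapply(c(90, 210, 330) * pi / 180, function(a)
  list(center = nc + 3.46 * c(cos(a), sin(a), 0), radius = 1.0))
spec <- phantom_spec(
  frame = c(72L, 72L), n_slices = 40L, pixel_size_xy = 0.35, z_step_air = 0.4,
  cells = list(phantom_cell(center = nc, radius = 7, nucleus_radius = 5,
                            fragments = frags, membrane = TRUE)),
  seed = 5)
ph  <- generate_phantom(spec)
res <- run_pipeline(stack = ph$stack)

round(res$morphometry[, c("V_c", "ER_c", "VSi_c", "V_n", "SVr_n", "CD_nc")], 3)
#>        V_c  ER_c VSi_c     V_n SVr_n CD_nc
#> 1 1441.235 7.007 0.665 400.722 1.798 0.049

f <- res$fragmentation[[1]]
sprintf("I_m = %d, I_th = %.1f (saturated: %s), valid voxels = %d, N_cl = %d",
        f$I_m, f$I_th, f$saturated, f$n_valid, f$n_cl)
#> "I_m = 4095, I_th = 4095.0 (saturated: TRUE), valid voxels = 292, N_cl = 3"
```

The recovered cell volume (1441 µm³) is within 0.4% of the analytic truth
(4/3·π·7³ ≈ 1437 µm³), VSi sits at the digital-ball limit 2/3, the cell is
classified apoptotic from its membrane fluorescence, and the cluster
division recovers exactly the three seeded fragments through the
saturation branch of the threshold rule.

A thin CLI over the same functions is installed at
`system.file("cli", "voxmorph", package = "voxmorph")` with subcommands
`simulate`, `segment`, `reconstruct`, `morph`, `frag`, `stats`, `run-all`.

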