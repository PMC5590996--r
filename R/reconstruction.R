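# Channel fusion, refraction correction of the z spacing, slice
# interpolation toward cubic voxels, lattice assembly, cell extraction and
# viability classification.

#' Fuse red- and green-channel cell masks of one slice
#'
#' The cytoplasmic outlines determined independently in the red and green
#' channels are compared and the one enclosing the bigger cell area is kept;
#' ties go to the red channel.
#'
#' @param red_map,green_map `slice_label_map`s of the same slice.
#' @return Logical cell mask.
#' @export
fuse_channels <- function(red_map, green_map) {
  red_cell <- red_map$labels > 0L
  green_cell <- green_map$labels > 0L
  if (sum(green_cell) > sum(red_cell)) green_cell else red_cell
}

#' Refraction-corrected z spacing
#'
#' Converts the nominal z step of the stage in air into the true distance
#' between consecutive image planes inside the aqueous sample, using a
#' refraction correction factor (default 0.87).
#'
#' @param z_step_air nominal z step in air, micrometres (> 0).
#' @param factor refraction correction factor.
#' @return True z spacing in micrometres.
#' @export
correct_z <- function(z_step_air, factor = 0.87) {
  if (!is.numeric(z_step_air) || any(z_step_air <= 0))
    stop("`z_step_air` must be > 0", call. = FALSE)
  factor * z_step_air
}

#' Assemble the labelled voxel lattice
#'
#' Combines the per-slice label maps with the acquired intensities into a 3D
#' voxel lattice. The z spacing is refraction-corrected, then
#' `m = round(dz_true / dx) - 1` extra planes are interpolated between each
#' acquired pair to make voxels as cubic as possible: intensities are
#' linearly interpolated along z while the categorical labels are copied
#' from the nearest acquired plane (ties toward the lower plane). The final
#' spacing is `dz = dz_true / (m + 1)`.
#'
#' Labels are assigned per acquired plane in the priority order cytoplasm <
#' membrane < mitochondrion < nucleus, with the membrane label restricted to
#' the part of the shell inside the fused cell mask so that the labelled
#' cell volume is not inflated.
#'
#' @param stack the `image_stack`.
#' @param red_maps,green_maps lists of `slice_label_map`s, one per acquired
#'   slice.
#' @param fused_masks list of logical cell masks from [fuse_channels()].
#' @param membrane_masks list of logical membrane masks from
#'   [membrane_mask()] (optional; empty membranes assumed if `NULL`).
#' @param refraction_factor correction factor passed to [correct_z()].
#' @return A [voxel_lattice()].
#' @export
build_lattice <- function(stack, red_maps, green_maps, fused_masks,
                          membrane_masks = NULL, refraction_factor = 0.87) {
  dm <- dim(stack$data)
  nz <- dm[4L]
  stopifnot(length(red_maps) == nz, length(green_maps) == nz,
            length(fused_masks) == nz)
  dx <- stack$pixel_size_xy
  dz_true <- correct_z(stack$z_step_air, refraction_factor)
  m <- max(0L, as.integer(round(dz_true / dx)) - 1L)
  dz <- dz_true / (m + 1L)
  nz_out <- (nz - 1L) * (m + 1L) + 1L
  acquired_z <- seq(1L, nz_out, by = m + 1L)

  lab_slices <- vector("list", nz)
  for (z in seq_len(nz)) {
    lab <- matrix(0L, dm[1L], dm[2L])
    cell <- fused_masks[[z]]
    lab[cell] <- label_codes[["cytoplasm"]]
    if (!is.null(membrane_masks)) lab[membrane_masks[[z]] & cell] <- label_codes[["membrane"]]
    lab[green_maps[[z]]$labels == 2L & cell] <- label_codes[["mitochondrion"]]
    lab[red_maps[[z]]$labels == 2L & cell] <- label_codes[["nucleus"]]
    lab_slices[[z]] <- lab
  }

  label <- array(0L, c(dm[1L], dm[2L], nz_out))
  intensity <- array(0L, c(dm[1L], dm[2L], nz_out, 3L))
  for (z in seq_len(nz)) {
    zo <- acquired_z[z]
    label[, , zo] <- lab_slices[[z]]
    for (ch in 1:3) intensity[, , zo, ch] <- stack$data[, , ch, z]
  }
  if (m > 0L) {
    for (z in seq_len(nz - 1L)) {
      for (j in seq_len(m)) {
        w <- j / (m + 1)
        zo <- acquired_z[z] + j
        nearest <- if (w <= 0.5) z else z + 1L
        label[, , zo] <- lab_slices[[nearest]]
        for (ch in 1:3)
          intensity[, , zo, ch] <- as.integer(round(
            (1 - w) * stack$data[, , ch, z] + w * stack$data[, , ch, z + 1L]))
      }
    }
  }
  voxel_lattice(label, intensity, c(dx, dx, dz), acquired_z)
}

#' Individual cell record
#'
#' One 26-connected cell extracted from a lattice: linear voxel indices of
#' the whole cell and of its nucleus, mitochondria and membrane subsets, a
#' truncation flag for cells touching the lattice boundary, and the
#' viability call (filled by [classify_viability()]).
#'
#' @param cell_id integer id.
#' @param voxels,nucleus,mitochondria,membrane linear voxel index vectors.
#' @param truncated logical flag.
#' @param viability `"viable"`, `"apoptotic"`, or `NA` if not yet classified.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_id, voxels, nucleus = integer(),
                        mitochondria = integer(), membrane = integer(),
                        truncated = FALSE, viability = NA_character_) {
  stopifnot(all(nucleus %in% voxels), all(mitochondria %in% voxels),
            all(membrane %in% voxels))
  structure(list(cell_id = as.integer(cell_id), voxels = voxels,
                 nucleus = nucleus, mitochondria = mitochondria,
                 membrane = membrane, truncated = isTRUE(truncated),
                 viability = viability),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf(
    "cell_record #%d: %d voxels (nucleus %d, mitochondria %d, membrane %d)%s, viability: %s\n",
    x$cell_id, length(x$voxels), length(x$nucleus), length(x$mitochondria),
    length(x$membrane), if (x$truncated) " [truncated]" else "", x$viability))
  invisible(x)
}

#' Extract individual cells from a labelled lattice
#'
#' Finds the 26-connected components of non-background voxels; each becomes
#' one [cell_record()] with its organelle subsets. Components touching the
#' lattice boundary are flagged truncated.
#'
#' @param lattice a `voxel_lattice`.
#' @param min_voxels drop components smaller than this many voxels
#'   (default 1, i.e. keep all).
#' @return List of `cell_record`s (possibly empty).
#' @export
extract_cells <- function(lattice, min_voxels = 1L) {
  dm <- dim(lattice$label)
  comp <- cc_label_3d(lattice$label != 0L, connectivity = 26L)
  ncomp <- max(comp)
  if (ncomp == 0L) return(list())
  cells <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    if (length(idx) < min_voxels) next
    a <- arrayInd(idx, dm)
    truncated <- any(a[, 1L] == 1L | a[, 1L] == dm[1L] |
                     a[, 2L] == 1L | a[, 2L] == dm[2L] |
                     a[, 3L] == 1L | a[, 3L] == dm[3L])
    labs <- lattice$label[idx]
    cells[[length(cells) + 1L]] <- cell_record(
      cell_id = length(cells) + 1L,
      voxels = idx,
      nucleus = idx[labs == label_codes[["nucleus"]]],
      mitochondria = idx[labs == label_codes[["mitochondrion"]]],
      membrane = idx[labs == label_codes[["membrane"]]],
      truncated = truncated
    )
  }
  cells
}

#' Blue-channel background statistics
#'
#' Mean and SD of the blue (Annexin V) channel over off-cell voxels, used as
#' the reference for the viability call.
#'
#' @param lattice a `voxel_lattice`.
#' @return List with `mean` and `sd`.
#' @export
background_blue_stats <- function(lattice) {
  off <- lattice$label == label_codes[["background"]]
  v <- lattice$intensity[, , , 3L][off]
  if (length(v) < 2L) stop("no off-cell voxels for background statistics",
                           call. = FALSE)
  list(mean = mean(v), sd = stats::sd(v))
}

#' Classify a cell as viable or apoptotic
#'
#' A cell is called apoptotic when the mean Annexin V (blue-channel)
#' intensity over its cytoplasmic-membrane voxels exceeds the off-cell
#' background mean by more than `k_sd` background standard deviations;
#' otherwise it is viable. An empty membrane set yields `"undetermined"`.
#'
#' @param cell a `cell_record`.
#' @param lattice the `voxel_lattice` it was extracted from.
#' @param background_stats list with `mean` and `sd` (default: computed by
#'   [background_blue_stats()]).
#' @param k_sd decision margin in background SDs (default 3).
#' @return The cell record with its `viability` field set.
#' @export
classify_viability <- function(cell, lattice, background_stats = NULL,
                               k_sd = 3) {
  if (is.null(background_stats)) background_stats <- background_blue_stats(lattice)
  if (length(cell$membrane) == 0L) {
    cell$viability <- "undetermined"
    return(cell)
  }
  blue <- lattice$intensity[, , , 3L][cell$membrane]
  cut <- background_stats$mean + k_sd * background_stats$sd
  cell$viability <- if (mean(blue) > cut) "apoptotic" else "viable"
  cell
}
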