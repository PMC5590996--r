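# Internal voxel-grid utilities shared across modules.

#' @importFrom stats sd kmeans pt rnorm rpois
NULL

# Organelle label codes used throughout the voxel lattice.
#' Organelle label codes
#'
#' Named integer vector mapping organelle names to the label codes stored in a
#' [voxel_lattice()]. `membrane` marks the Annexin V shell voxels on the
#' cytoplasmic membrane (a subset of the cell, disjoint from nucleus and
#' mitochondria).
#'
#' @export
label_codes <- c(
  background    = 0L,
  cytoplasm     = 1L,
  nucleus       = 2L,
  mitochondrion = 3L,
  membrane      = 4L
)

# Physical coordinates (um) of voxel centers for linear indices into a 3D
# array of dimension `dm`. Axis order of dm is (y, x, z) matching how TIFF
# slices are stored (rows = y); returned columns are (x, y, z) in um.
voxel_centers <- function(idx, dm, voxel_size) {
  a <- arrayInd(idx, dm)
  cbind(
    x = (a[, 2L] - 0.5) * voxel_size[1L],
    y = (a[, 1L] - 0.5) * voxel_size[2L],
    z = (a[, 3L] - 0.5) * voxel_size[3L]
  )
}

# Neighbor offsets (as (dy, dx, dz) triples) for 6- or 26-connectivity.
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# Connected-component labelling of a 3D logical array. EBImage's bwlabel is
# 2D-only, so this is a vectorized breadth-first flood fill over voxel
# coordinates. Returns an integer array of component ids (0 = background).
cc_label_3d <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  lab <- array(0L, dm)
  todo <- which(mask)
  if (length(todo) == 0L) return(lab)
  offs <- neighbor_offsets(connectivity)
  comp <- 0L
  remaining <- array(FALSE, dm)
  remaining[todo] <- TRUE
  for (seed in todo) {
    if (!remaining[seed]) next
    comp <- comp + 1L
    frontier <- seed
    remaining[seed] <- FALSE
    lab[seed] <- comp
    while (length(frontier) > 0L) {
      a <- arrayInd(frontier, dm)
      # expand all frontier voxels by all offsets at once
      n <- nrow(a) * nrow(offs)
      yy <- rep(a[, 1L], each = nrow(offs)) + rep(offs[, 1L], times = nrow(a))
      xx <- rep(a[, 2L], each = nrow(offs)) + rep(offs[, 2L], times = nrow(a))
      zz <- rep(a[, 3L], each = nrow(offs)) + rep(offs[, 3L], times = nrow(a))
      ok <- yy >= 1L & yy <= dm[1L] & xx >= 1L & xx <= dm[2L] &
        zz >= 1L & zz <= dm[3L]
      cand <- unique((zz[ok] - 1L) * dm[1L] * dm[2L] + (xx[ok] - 1L) * dm[1L] + yy[ok])
      cand <- cand[remaining[cand]]
      if (length(cand) > 0L) {
        remaining[cand] <- FALSE
        lab[cand] <- comp
      }
      frontier <- cand
    }
  }
  lab
}

# Logical 3D array from a set of linear indices.
mask_from_idx <- function(idx, dm) {
  m <- array(FALSE, dm)
  m[idx] <- TRUE
  m
}

# Exposed-face counts of a voxel set along each axis, used for surface area
# and membrane-voxel extraction. Returns list(mask, faces = c(y, x, z) counts,
# boundary = linear indices of voxels with >= 1 exposed face).
face_analysis <- function(idx, dm) {
  m <- mask_from_idx(idx, dm)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1), drop = FALSE]
  exposed <- array(0L, dm)
  faces <- c(y = 0L, x = 0L, z = 0L)
  shifts <- list(
    y = list(c(1L, 0L, 0L), c(-1L, 0L, 0L)),
    x = list(c(0L, 1L, 0L), c(0L, -1L, 0L)),
    z = list(c(0L, 0L, 1L), c(0L, 0L, -1L))
  )
  for (ax in names(shifts)) {
    for (s in shifts[[ax]]) {
      nb <- pad[2:(dm[1] + 1) + s[1], 2:(dm[2] + 1) + s[2], 2:(dm[3] + 1) + s[3],
                drop = FALSE]
      ex <- core & !nb
      faces[ax] <- faces[ax] + sum(ex)
      exposed <- exposed + ex
    }
  }
  list(faces = faces, boundary = which(exposed > 0L & m))
}

# Five-point cubic (Savitzky-Golay) smoothing of a closed (circular) signal.
circ_smooth5 <- function(v) {
  k <- c(-3, 12, 17, 12, -3) / 35
  n <- length(v)
  if (n < 5L) return(v)
  ext <- c(v[(n - 1):n], v, v[1:2])
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(ext[i:(i + 4)] * k)
  out
}

# Deterministic sub-seed derived from a base seed and a node path, kept below
# 2^31 so set.seed() accepts it.
derive_seed <- function(seed, path) {
  h <- as.double(seed %% 2147483647L)
  for (b in path) h <- (h * 31 + b + 7) %% 2147483647
  as.integer(h)
}
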