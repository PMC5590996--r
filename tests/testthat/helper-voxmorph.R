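# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# Linear indices of a digital ball (voxel centers within radius r of
# `center`, in index units) inside a lattice of dimension dm = (ny, nx, nz).
ball_idx <- function(dm, center, r) {
  idx <- which(array(TRUE, dm))
  a <- arrayInd(idx, dm)
  d2 <- (a[, 1] - center[1])^2 + (a[, 2] - center[2])^2 + (a[, 3] - center[3])^2
  idx[d2 <= r^2]
}

# Minimal lattice holding the given index sets with the given label codes
# and a constant (or supplied) red intensity.
make_lattice <- function(dm, sets, voxel_size = c(1, 1, 1),
                         red = NULL, green = NULL, blue = NULL) {
  label <- array(0L, dm)
  for (nm in names(sets)) label[sets[[nm]]] <- label_codes[[nm]]
  intensity <- array(0L, c(dm, 3L))
  if (!is.null(red)) intensity[, , , 1L] <- red
  if (!is.null(green)) intensity[, , , 2L] <- green
  if (!is.null(blue)) intensity[, , , 3L] <- blue
  voxel_lattice(label, intensity, voxel_size)
}

# Between-class variance of a pixel vector at a given threshold.
between_class_variance <- function(px, t) {
  lo <- px[px < t]
  hi <- px[px >= t]
  if (length(lo) == 0L || length(hi) == 0L) return(0)
  w0 <- length(lo) / length(px)
  w0 * (1 - w0) * (mean(hi) - mean(lo))^2
}

# Independent Otsu oracle: exhaustive scan of the between-class variance
# over all integer thresholds.
otsu_scan_oracle <- function(px) {
  cands <- seq(min(px) + 1L, max(px))
  best <- cands[1]
  best_v <- -Inf
  n <- length(px)
  for (t in cands) {
    lo <- px[px < t]
    hi <- px[px >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    v <- w0 * (1 - w0) * (mean(hi) - mean(lo))^2
    if (v > best_v) {
      best_v <- v
      best <- t
    }
  }
  best
}

# Independent triple-loop oracle for the number of lattice sites inside a
# closed sphere (centers at (i + 0.5) * d per axis). The squared radius is
# passed exactly, matching the definition "sphere reaching the furthest
# member".
brute_sphere_count <- function(centroid, radius, voxel_size, r2 = radius^2) {
  total <- 0L
  rng <- function(c0, d) {
    lo <- floor((c0 - radius) / d - 0.5) - 2L
    hi <- ceiling((c0 + radius) / d - 0.5) + 2L
    lo:hi
  }
  for (i in rng(centroid[1], voxel_size[1]))
    for (j in rng(centroid[2], voxel_size[2]))
      for (k in rng(centroid[3], voxel_size[3])) {
        x <- (i + 0.5) * voxel_size[1]
        y <- (j + 0.5) * voxel_size[2]
        z <- (k + 0.5) * voxel_size[3]
        if ((x - centroid[1])^2 + (y - centroid[2])^2 + (z - centroid[3])^2 <= r2)
          total <- total + 1L
      }
  total
}

# Frame with a bright disk inside a dimmer annulus on zero background.
disk_annulus_frame <- function(n = 128, r_disk = 30, r_annulus = 50,
                               i_disk = 2000, i_annulus = 400) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- (i - n / 2)^2 + (j - n / 2)^2
    if (d2 <= r_disk^2) m[i, j] <- i_disk
    else if (d2 <= r_annulus^2) m[i, j] <- i_annulus
  }
  m
}

# Small two-cell phantom reused by reconstruction and pipeline tests.
two_cell_phantom <- function(seed = 11) {
  phantom_spec(
    frame = c(96L, 96L), n_slices = 30L, pixel_size_xy = 0.4, z_step_air = 0.5,
    cells = list(
      phantom_cell(center = c(12, 12, 6.5), radius = 5.5, nucleus_radius = 3.2,
                   n_mito = 4, membrane = FALSE),
      phantom_cell(center = c(26, 26, 6.5), radius = 5.5, nucleus_radius = 3.2,
                   n_mito = 4, membrane = TRUE)
    ),
    seed = seed
  )
}

# Fragmented apoptotic single-cell phantom: three saturating chromatin
# fragments in a dim gradient envelope.
fragmented_phantom <- function(seed = 5) {
  nc <- c(12.6, 12.6, 7)
  ang <- c(90, 210, 330) * pi / 180
  frags <- lapply(ang, function(a)
    list(center = nc + 3.46 * c(cos(a), sin(a), 0), radius = 1.0))
  phantom_spec(
    frame = c(72L, 72L), n_slices = 40L, pixel_size_xy = 0.35, z_step_air = 0.4,
    cells = list(phantom_cell(center = nc, radius = 7, nucleus_radius = 5,
                              fragments = frags, membrane = TRUE)),
    seed = seed
  )
}

# Well-separated fragment layouts (ball centers in index units) used by the
# cluster-recovery checks: balls of radius 5 voxels, pairwise center
# separations >= 30 voxels.
fragment_layouts <- function() {
  list(
    list(c(25, 40, 25)),
    list(c(25, 20, 25), c(25, 50, 25)),
    list(c(10, 10, 25), c(10, 70, 25), c(40, 40, 25)),
    list(c(10, 10, 25), c(10, 70, 25), c(40, 10, 25), c(40, 70, 25)),
    list(c(10, 10, 25), c(10, 70, 25), c(40, 10, 25), c(40, 70, 25),
         c(25, 40, 25))
  )
}

fragment_coords <- function(centers, dm = c(50L, 80L, 50L), r = 5) {
  idx <- unlist(lapply(centers, function(cen) ball_idx(dm, cen, r)))
  voxmorph:::voxel_centers(idx, dm, c(1, 1, 1))
}

# Random compact voxel cluster with measured density above a floor:
# a digital ball with a random subset of boundary voxels removed stays
# nearly solid, so its density exceeds 2/3.
random_dense_cluster <- function(dm = c(32L, 32L, 32L)) {
  r <- stats::runif(1, 2, 5)
  cen <- stats::runif(3, r + 2, dm - r - 2)
  idx <- ball_idx(dm, cen, r)
  keep <- stats::runif(length(idx)) > 0.03
  idx <- idx[keep]
  voxmorph:::voxel_centers(idx, dm, c(1, 1, 1))
}
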