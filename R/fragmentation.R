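# Quantification of nuclear fragmentation: the nuclear-stain intensity
# histogram is smoothed with a five-point cubic window, a threshold I_th is
# derived from the histogram mode and its 5% fall-off (with a saturation
# branch at the 12-bit ceiling), nuclear voxels are binarized into valid /
# null, and the valid voxels are divided into clusters by a recursive
# 2-means scheme whose splits are accepted only when the mean density of the
# two daughter clusters is at least 1.5 times the parent's density. The
# number of leaf clusters N_cl quantifies fragmentation.

#' Intensity histogram of the nuclear voxels
#'
#' Compiles the red-channel (nuclear stain) intensities of a cell's nucleus
#' voxels into a histogram at bin width 1 over `[0, 4095]` and smooths it
#' with a cubic polynomial fit over a sliding five-point window
#' (Savitzky-Golay).
#'
#' @param cell a `cell_record` with a non-empty nucleus.
#' @param lattice the `voxel_lattice`.
#' @return Object of class `nuclear_histogram`: list with `intensity`
#'   (0:4095), `counts` (raw) and `smoothed`.
#' @export
nuclear_histogram <- function(cell, lattice) {
  if (length(cell$nucleus) == 0L) stop("empty nucleus", call. = FALSE)
  v <- lattice$intensity[, , , 1L][cell$nucleus]
  counts <- tabulate(as.integer(v) + 1L, nbins = 4096L)
  smoothed <- signal::sgolayfilt(counts, p = 3L, n = 5L)
  structure(list(intensity = 0:4095, counts = counts, smoothed = smoothed),
            class = "nuclear_histogram")
}

#' @export
print.nuclear_histogram <- function(x, ...) {
  cat(sprintf("nuclear_histogram: %d voxels, smoothed mode at %d\n",
              sum(x$counts), which.max(x$smoothed) - 1L))
  invisible(x)
}

#' Binarization threshold from a nuclear histogram
#'
#' Finds the mode `I_m` of the smoothed histogram, scans toward increasing
#' intensity for `I_5pct`, the first intensity at which the smoothed count
#' has fallen to 5% of the maximum or below, and sets
#' `I_th = (I_m + I_5pct) / 2`. If the count never falls to 5% before the
#' 12-bit saturation value 4095, `I_th = (I_m + 4095) / 2` and the result is
#' flagged saturated. A histogram with a single occupied bin is degenerate:
#' `I_th` equals that intensity (all voxels valid).
#'
#' @param hist a `nuclear_histogram`.
#' @return List with `I_th`, `I_m`, `I_5pct` (`NA` on the saturated or
#'   degenerate branch), `saturated` and `degenerate` flags.
#' @export
determine_threshold <- function(hist) {
  if (all(hist$counts == 0L)) stop("no nucleus signal in histogram", call. = FALSE)
  nz <- which(hist$counts > 0L)
  if (length(nz) == 1L) {
    val <- hist$intensity[nz]
    return(list(I_th = as.numeric(val), I_m = as.numeric(val),
                I_5pct = NA_real_, saturated = FALSE, degenerate = TRUE))
  }
  imax <- which.max(hist$smoothed)
  I_m <- hist$intensity[imax]
  cut <- 0.05 * hist$smoothed[imax]
  above <- hist$intensity > I_m & hist$smoothed <= cut
  if (any(above)) {
    I_5pct <- hist$intensity[which(above)[1L]]
    list(I_th = (I_m + I_5pct) / 2, I_m = as.numeric(I_m),
         I_5pct = as.numeric(I_5pct), saturated = FALSE, degenerate = FALSE)
  } else {
    list(I_th = (I_m + 4095) / 2, I_m = as.numeric(I_m),
         I_5pct = NA_real_, saturated = TRUE, degenerate = FALSE)
  }
}

#' Binarize nuclear voxels into valid and null
#'
#' Nuclear voxels whose red-channel intensity is at or above `I_th` are
#' "valid"; the rest are "null". An empty valid set is returned with a
#' warning (fragmentation is then undefined).
#'
#' @param cell a `cell_record`.
#' @param lattice the `voxel_lattice`.
#' @param I_th threshold from [determine_threshold()].
#' @return Linear indices of the valid voxels.
#' @export
binarize_nucleus <- function(cell, lattice, I_th) {
  v <- lattice$intensity[, , , 1L][cell$nucleus]
  valid <- cell$nucleus[v >= I_th]
  if (length(valid) == 0L)
    warning("empty valid set: all nuclear voxels below I_th", call. = FALSE)
  valid
}

#' Sphere density of a voxel cluster
#'
#' Density rho of a cluster of valid voxels: the centroid of the member
#' voxel centers is computed, the cluster radius is the distance of the
#' furthest member from the centroid, and rho is the ratio of the member
#' count to the number of lattice sites (the infinite geometric grid with
#' the lattice's voxel spacing, not restricted to the nucleus or the stack)
#' whose centers lie within the closed sphere. A single-voxel cluster has
#' rho = 1 by convention.
#'
#' @param coords n x 3 matrix of member voxel centers (x, y, z in um), e.g.
#'   from [valid_coords()].
#' @param voxel_size `c(dx, dy, dz)` in um.
#' @return List with `rho`, `centroid`, `radius` and `n_sphere` (the
#'   denominator).
#' @export
cluster_density <- function(coords, voxel_size) {
  coords <- rbind(coords)
  n <- nrow(coords)
  if (n == 0L) stop("empty cluster", call. = FALSE)
  centroid <- colMeans(coords)
  d2 <- (coords[, 1] - centroid[1])^2 + (coords[, 2] - centroid[2])^2 +
    (coords[, 3] - centroid[3])^2
  r2 <- max(d2)
  radius <- sqrt(r2)
  if (n == 1L)
    return(list(rho = 1, centroid = centroid, radius = 0, r2 = 0,
                n_sphere = 1L))
  # count with the exact squared radius: squaring sqrt(max(d2)) can fall
  # below max(d2), which would drop boundary members from their own sphere
  # and push rho above 1
  n_sphere <- sphere_site_count(centroid, radius, voxel_size, r2 = r2)
  list(rho = n / n_sphere, centroid = centroid, radius = radius, r2 = r2,
       n_sphere = n_sphere)
}

# Number of geometric lattice sites (centers at (i + 0.5) * d per axis, i
# any integer) within the closed sphere. Enumerates the bounding box one z
# plane at a time.
sphere_site_count <- function(centroid, radius, voxel_size, r2 = radius^2) {
  ax_range <- function(c0, d) {
    # one spare site each side; the distance test filters exactly
    lo <- ceiling((c0 - radius) / d - 0.5) - 1L
    hi <- floor((c0 + radius) / d - 0.5) + 1L
    if (hi < lo) integer() else lo:hi
  }
  is_ <- ax_range(centroid[1], voxel_size[1])
  js <- ax_range(centroid[2], voxel_size[2])
  ks <- ax_range(centroid[3], voxel_size[3])
  if (!length(is_) || !length(js) || !length(ks)) return(0L)
  xs <- (is_ + 0.5) * voxel_size[1]
  ys <- (js + 0.5) * voxel_size[2]
  total <- 0L
  for (zk in (ks + 0.5) * voxel_size[3]) {
    dz2 <- (zk - centroid[3])^2
    dx2 <- (xs - centroid[1])^2
    dy2 <- (ys - centroid[2])^2
    total <- total + sum(outer(dx2, dy2, `+`) + dz2 <= r2)
  }
  total
}

#' Voxel centers of a valid set
#'
#' Convenience converter from linear voxel indices to the physical (um)
#' coordinates used by the clustering.
#'
#' @param idx linear voxel indices.
#' @param lattice the `voxel_lattice`.
#' @return n x 3 coordinate matrix.
#' @export
valid_coords <- function(idx, lattice) {
  voxel_centers(idx, dim(lattice$label), lattice$voxel_size)
}

#' Density-criterion recursive cluster division
#'
#' Starting from all valid voxels as one cluster, each current leaf is
#' tentatively partitioned into two daughter clusters by 2-means on the
#' physical voxel coordinates. Candidate bipartitions come from 10
#' random-initialization Lloyd runs (deterministic sub-seeds derived from
#' the seed and the node's tree path) plus one deterministic run
#' initialized at the two mutually furthest members; among the converged
#' candidates the one with the largest mean daughter density is taken,
#' which is the method's own objective and in particular lets an isolated
#' stray voxel be split off instead of shattering a compact fragment (plain
#' within-sum-of-squares selection systematically prefers the latter). The
#' chosen split is accepted if and only if the mean of the two daughter
#' densities is at least `density_gain` (default 1.5) times the parent
#' density, and accepted daughters are divided recursively. Leaves of size
#' 1 are never split. Because densities are bounded by 1 and each accepted
#' split multiplies the density by at least 1.5, the recursion always
#' terminates; in particular any cluster with rho > 2/3 is necessarily a
#' leaf.
#'
#' `n_cl` counts the leaves holding at least `min_leaf_frac` of the valid
#' voxels; tiny residual leaves (e.g. single voxels cut off a fragment
#' boundary by a k-means plane) are reported in `leaves` but not counted as
#' fragments.
#'
#' @param coords n x 3 matrix of valid voxel centers (um), or a vector of
#'   linear indices together with `lattice`.
#' @param voxel_size `c(dx, dy, dz)` in um (ignored when `lattice` given).
#' @param seed integer seed controlling the 2-means restarts.
#' @param density_gain acceptance factor for the mean daughter density.
#' @param n_restarts random-initialization 2-means runs per tentative split.
#' @param min_leaf_frac smallest fraction of the valid set a leaf must hold
#'   to count toward `n_cl` (default 0.01).
#' @param lattice optional `voxel_lattice` when `coords` is an index vector.
#' @return Object of class `cluster_result`: list with `n_cl`, `leaves`
#'   (per-leaf `size`, `centroid`, `rho`), the full `root` tree and `seed`.
#' @export
split_clusters <- function(coords, voxel_size = NULL, seed = 1L,
                           density_gain = 1.5, n_restarts = 10L,
                           min_leaf_frac = 0.01, lattice = NULL) {
  if (!is.null(lattice)) {
    coords <- valid_coords(coords, lattice)
    voxel_size <- lattice$voxel_size
  }
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty valid set", call. = FALSE)
  if (is.null(voxel_size)) stop("`voxel_size` required", call. = FALSE)

  divide <- function(rows, path) {
    dens <- cluster_density(coords[rows, , drop = FALSE], voxel_size)
    node <- list(members = rows, rho = dens$rho, centroid = dens$centroid,
                 radius = dens$radius, children = NULL)
    n <- length(rows)
    if (n < 2L || nrow(unique(coords[rows, , drop = FALSE])) < 2L) return(node)
    pts <- coords[rows, , drop = FALSE]
    best <- NULL
    best_mean <- -Inf
    for (part in candidate_2means(pts, seed, path, n_restarts, voxel_size)) {
      d1 <- cluster_density(pts[part == 1L, , drop = FALSE], voxel_size)
      d2 <- cluster_density(pts[part == 2L, , drop = FALSE], voxel_size)
      m <- (d1$rho + d2$rho) / 2
      if (m > best_mean) {
        best_mean <- m
        best <- part
      }
    }
    if (!is.null(best) && best_mean >= density_gain * dens$rho) {
      rows1 <- rows[best == 1L]; rows2 <- rows[best == 2L]
      node$children <- list(divide(rows1, c(path, 1L)),
                            divide(rows2, c(path, 2L)))
    }
    node
  }
  root <- divide(seq_len(nrow(coords)), integer())

  leaves <- list()
  walk <- function(node) {
    if (is.null(node$children)) {
      leaves[[length(leaves) + 1L]] <<- list(
        size = length(node$members), centroid = node$centroid,
        rho = node$rho, members = node$members)
    } else {
      walk(node$children[[1L]]); walk(node$children[[2L]])
    }
  }
  walk(root)
  min_count <- max(1L, as.integer(ceiling(min_leaf_frac * nrow(coords))))
  n_cl <- sum(vapply(leaves, function(l) l$size, integer(1)) >= min_count)
  structure(list(root = root, n_cl = n_cl, leaves = leaves,
                 seed = as.integer(seed)),
            class = "cluster_result")
}

# Candidate 2-means bipartitions of a point set: n_restarts random
# initializations (deterministic sub-seeds), one run initialized at the two
# mutually furthest points (so an isolated stray can seed its own side),
# and, when the set has several 26-connected components, a
# connectivity-respecting grouping of whole components (2-means on the
# component centroids) that never slices a compact fragment. Returns a list
# of 1/2 assignment vectors.
candidate_2means <- function(pts, seed, path, n_restarts, voxel_size) {
  out <- list()
  run <- function(expr) {
    km <- tryCatch(expr, error = function(e) NULL)
    if (!is.null(km) && min(km$size) > 0L) out[[length(out) + 1L]] <<- km$cluster
  }
  for (r in seq_len(n_restarts)) {
    s <- derive_seed(seed, c(path, 100L + r))
    run({
      set.seed(s)
      stats::kmeans(pts, centers = 2L, iter.max = 100L, nstart = 1L)
    })
  }
  cen <- colMeans(pts)
  i1 <- which.max(rowSums((pts - rep(cen, each = nrow(pts)))^2))
  i2 <- which.max(rowSums((pts - rep(pts[i1, ], each = nrow(pts)))^2))
  if (i1 != i2)
    run(stats::kmeans(pts, centers = pts[c(i1, i2), , drop = FALSE],
                      iter.max = 100L))
  cc <- component_partition(pts, voxel_size)
  if (!is.null(cc)) out[[length(out) + 1L]] <- cc
  out
}

# Bipartition whole 26-connected components of the voxel set (NULL when the
# set is a single component). Components are grouped into two sides by
# 2-means on their centroids, initialized at the two mutually furthest
# centroids.
component_partition <- function(pts, voxel_size) {
  ijk <- cbind(round(pts[, 2] / voxel_size[2] - 0.5),
               round(pts[, 1] / voxel_size[1] - 0.5),
               round(pts[, 3] / voxel_size[3] - 0.5))
  off <- apply(ijk, 2L, min) - 1L
  ijk <- sweep(ijk, 2L, off)
  dm <- apply(ijk, 2L, max) + 1L
  lin <- (ijk[, 3] - 1L) * dm[1L] * dm[2L] + (ijk[, 2] - 1L) * dm[1L] + ijk[, 1]
  comp_arr <- cc_label_3d(mask_from_idx(lin, dm), connectivity = 26L)
  comp <- comp_arr[lin]
  ncomp <- max(comp)
  if (ncomp < 2L) return(NULL)
  if (ncomp == 2L) return(comp)
  cents <- t(vapply(seq_len(ncomp), function(k)
    colMeans(pts[comp == k, , drop = FALSE]), numeric(3L)))
  c1 <- which.max(rowSums((cents - rep(colMeans(cents), each = ncomp))^2))
  c2 <- which.max(rowSums((cents - rep(cents[c1, ], each = ncomp))^2))
  km <- tryCatch(stats::kmeans(cents, centers = cents[c(c1, c2), , drop = FALSE],
                               iter.max = 100L),
                 error = function(e) NULL)
  if (is.null(km) || min(km$size) == 0L) return(NULL)
  km$cluster[comp]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: N_cl = %d (leaf sizes: %s)\n", x$n_cl,
              paste(vapply(x$leaves, function(l) l$size, integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Full fragmentation analysis of one cell
#'
#' Runs histogram compilation, threshold determination, binarization and
#' cluster division for one reconstructed cell.
#'
#' @param cell a `cell_record` with non-empty nucleus.
#' @param lattice the `voxel_lattice`.
#' @param seed clustering seed.
#' @param density_gain acceptance factor (see [split_clusters()]).
#' @return List with `n_cl`, `I_th`, `I_m`, `I_5pct`, `saturated`,
#'   `degenerate`, `n_valid`, and `clusters` (the `cluster_result`).
#' @export
analyze_fragmentation <- function(cell, lattice, seed = 1L,
                                  density_gain = 1.5) {
  hist <- nuclear_histogram(cell, lattice)
  th <- determine_threshold(hist)
  valid <- binarize_nucleus(cell, lattice, th$I_th)
  if (length(valid) == 0L)
    return(c(th, list(n_cl = NA_integer_, n_valid = 0L, clusters = NULL)))
  res <- split_clusters(valid, seed = seed, density_gain = density_gain,
                        lattice = lattice)
  c(th, list(n_cl = res$n_cl, n_valid = length(valid), clusters = res))
}
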