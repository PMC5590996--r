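# Synthetic three-channel confocal stack generator with analytic ground
# truth. Phantoms emulate triple-stained suspended cells: an ellipsoidal
# cell body with diffuse nuclear-stain signal in the cytoplasm (red), a
# nuclear envelope containing optional bright compact fragments (red),
# scattered mitochondrial blobs (green), and an optional membrane-localized
# apoptosis signal (blue), with Gaussian and/or Poisson noise and 12-bit
# clipping at 4095. Slice geometry is sampled at the true (refraction-
# corrected) plane spacing while the stack metadata records the nominal air
# step, mirroring real acquisition.

#' One phantom cell description
#'
#' @param center cell center `c(x, y, z)` in um.
#' @param radius sphere radius in um (shorthand for equal `semi_axes`).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` in um (overrides
#'   `radius`).
#' @param nucleus_radius nuclear envelope radius in um (`NULL` for no
#'   nucleus).
#' @param nucleus_center nucleus center (default: cell center).
#' @param fragments optional list of `list(center = c(x, y, z), radius = r)`
#'   bright nuclear fragments, which must lie inside the nuclear envelope.
#' @param n_mito number of mitochondrial blobs.
#' @param mito_radius radius range `c(min, max)` in um for the blobs.
#' @param membrane logical: render the membrane-localized apoptosis signal.
#' @return A list of class `phantom_cell`.
#' @export
phantom_cell <- function(center, radius = NULL, semi_axes = NULL,
                         nucleus_radius = NULL, nucleus_center = center,
                         fragments = NULL, n_mito = 0L,
                         mito_radius = c(0.5, 1), membrane = FALSE) {
  if (is.null(semi_axes)) {
    if (is.null(radius)) stop("give `radius` or `semi_axes`", call. = FALSE)
    semi_axes <- rep(radius, 3L)
  }
  if (!is.null(fragments)) {
    if (is.null(nucleus_radius))
      stop("fragments require a nuclear envelope", call. = FALSE)
    for (f in fragments) {
      if (sqrt(sum((f$center - nucleus_center)^2)) + f$radius >
          nucleus_radius + 1e-9)
        stop("fragment extends outside the nuclear envelope", call. = FALSE)
    }
  }
  structure(list(center = center, semi_axes = semi_axes,
                 nucleus_radius = nucleus_radius,
                 nucleus_center = nucleus_center, fragments = fragments,
                 n_mito = as.integer(n_mito), mito_radius = mito_radius,
                 membrane = isTRUE(membrane)),
            class = "phantom_cell")
}

default_phantom_intensities <- function() {
  list(
    red = c(background = 20, cytoplasm = 600, nucleus = 1200, fragment = 4300),
    green = c(background = 20, cytoplasm = 300, mitochondrion = 2200),
    blue = c(background = 15, membrane = 1800)
  )
}

#' Phantom stack specification
#'
#' @param frame frame size `c(ny, nx)` in pixels.
#' @param n_slices number of acquired z slices.
#' @param pixel_size_xy xy pixel size in um.
#' @param z_step_air nominal z step in air in um.
#' @param refraction_factor factor relating air step to true plane spacing.
#' @param cells list of [phantom_cell()]s; cell bodies must not overlap.
#' @param intensities per-compartment channel means (see
#'   `voxmorph:::default_phantom_intensities`); partial lists are merged
#'   into the defaults.
#' @param noise list with `gaussian_sd` (additive Gaussian noise SD,
#'   intensity units) and `poisson` (logical: Poisson photon noise).
#' @param membrane_thickness thickness of the blue membrane band (um),
#'   placed just inside the cell surface.
#' @param envelope_gradient relative dimming of the nuclear envelope at its
#'   center for fragmented nuclei: the envelope intensity rises linearly
#'   from `(1 - g)` of the nominal nucleus intensity at the center to the
#'   full value at the rim (peripheral-heterochromatin-like staining). This
#'   gives the envelope histogram a sharp upper flank so that the
#'   5%-fall-off binarization isolates the bright fragments.
#' @param seed integer; fixes all randomness of the generator.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(frame = c(128L, 128L), n_slices = 40L,
                         pixel_size_xy = 0.4, z_step_air = 0.5,
                         refraction_factor = 0.87, cells = list(),
                         intensities = list(),
                         noise = list(gaussian_sd = 15, poisson = FALSE),
                         membrane_thickness = 0.8, envelope_gradient = 0.25,
                         seed = 1L) {
  ints <- default_phantom_intensities()
  for (ch in names(intensities)) {
    v <- intensities[[ch]]
    ints[[ch]][names(v)] <- v
  }
  if (length(cells) > 1L) {
    for (i in seq_along(cells)) for (j in seq_len(i - 1L)) {
      d <- sqrt(sum((cells[[i]]$center - cells[[j]]$center)^2))
      if (d < max(cells[[i]]$semi_axes) + max(cells[[j]]$semi_axes))
        stop("overlapping phantom cells are unsupported", call. = FALSE)
    }
  }
  nd <- list(gaussian_sd = 15, poisson = FALSE)
  nd[names(noise)] <- noise
  structure(list(frame = as.integer(frame), n_slices = as.integer(n_slices),
                 pixel_size_xy = pixel_size_xy, z_step_air = z_step_air,
                 refraction_factor = refraction_factor, cells = cells,
                 intensities = ints, noise = nd,
                 membrane_thickness = membrane_thickness,
                 envelope_gradient = envelope_gradient,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Sample mitochondrial blob centers/radii for one cell: uniform inside the
# (slightly shrunk) cell ellipsoid, outside the nuclear envelope.
place_mitochondria <- function(cell, spec) {
  if (cell$n_mito == 0L) return(list())
  out <- list()
  tries <- 0L
  while (length(out) < cell$n_mito && tries < 2000L) {
    tries <- tries + 1L
    r <- stats::runif(1, cell$mito_radius[1], cell$mito_radius[2])
    u <- stats::runif(3, -1, 1)
    p <- cell$center + u * (cell$semi_axes - r)
    e <- sum(((p - cell$center) / pmax(cell$semi_axes - r, 1e-6))^2)
    if (e > 1) next
    if (!is.null(cell$nucleus_radius) &&
        sqrt(sum((p - cell$nucleus_center)^2)) < cell$nucleus_radius + r) next
    out[[length(out) + 1L]] <- list(center = p, radius = r)
  }
  out
}

#' Generate a phantom stack with ground truth
#'
#' Rasterizes the phantom geometry into an [image_stack()] (12-bit, three
#' channels) and returns it together with a per-cell truth table and a
#' per-slice truth label volume (codes as [label_codes], plus 5 for nuclear
#' fragment voxels).
#'
#' Condensed-chromatin fragments (and intact bright nuclei) are rendered at
#' intensities above the 12-bit ceiling by default, so their voxels
#' saturate at 4095 — the situation the threshold rule's saturation branch
#' handles — while the degraded nuclear envelope stays in the dim,
#' unsaturated range with its rim-weighted gradient.
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack`, `truth` (data.frame: per-cell analytic volumes,
#'   fragment count, viability, centers), `truth_label` (integer array
#'   `(ny, nx, n_slices)`) and `mitochondria` (the sampled blob list).
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  ny <- spec$frame[1L]; nx <- spec$frame[2L]; nz <- spec$n_slices
  px <- spec$pixel_size_xy
  dz_true <- spec$refraction_factor * spec$z_step_air
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  ints <- spec$intensities
  mitos <- lapply(spec$cells, place_mitochondria, spec = spec)

  data <- array(0L, c(ny, nx, 3L, nz))
  truth_label <- array(0L, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    z <- (k - 0.5) * dz_true
    red <- matrix(ints$red[["background"]], ny, nx)
    green <- matrix(ints$green[["background"]], ny, nx)
    blue <- matrix(ints$blue[["background"]], ny, nx)
    tl <- matrix(0L, ny, nx)
    for (ci in seq_along(spec$cells)) {
      cell <- spec$cells[[ci]]
      a <- cell$semi_axes
      e2 <- ((X - cell$center[1]) / a[1])^2 + ((Y - cell$center[2]) / a[2])^2 +
        ((z - cell$center[3]) / a[3])^2
      inside <- e2 <= 1
      if (!any(inside)) next
      red[inside] <- ints$red[["cytoplasm"]]
      green[inside] <- ints$green[["cytoplasm"]]
      tl[inside] <- label_codes[["cytoplasm"]]
      if (cell$membrane) {
        ai <- pmax(a - spec$membrane_thickness, 0.1)
        e2i <- ((X - cell$center[1]) / ai[1])^2 +
          ((Y - cell$center[2]) / ai[2])^2 + ((z - cell$center[3]) / ai[3])^2
        band <- inside & e2i > 1
        blue[band] <- ints$blue[["membrane"]]
        tl[band] <- label_codes[["membrane"]]
      }
      for (mb in mitos[[ci]]) {
        d2 <- (X - mb$center[1])^2 + (Y - mb$center[2])^2 + (z - mb$center[3])^2
        hit <- d2 <= mb$radius^2
        green[hit] <- ints$green[["mitochondrion"]]
        tl[hit] <- label_codes[["mitochondrion"]]
      }
      if (!is.null(cell$nucleus_radius)) {
        d2 <- (X - cell$nucleus_center[1])^2 + (Y - cell$nucleus_center[2])^2 +
          (z - cell$nucleus_center[3])^2
        nuc <- d2 <= cell$nucleus_radius^2
        if (is.null(cell$fragments)) {
          # intact nucleus: uniformly bright chromatin
          red[nuc] <- ints$red[["fragment"]]
        } else {
          # degraded envelope: dim center, bright rim
          g <- spec$envelope_gradient
          frac <- sqrt(d2[nuc]) / cell$nucleus_radius
          red[nuc] <- ints$red[["nucleus"]] * (1 - g * (1 - frac))
        }
        tl[nuc] <- label_codes[["nucleus"]]
        if (!is.null(cell$fragments)) {
          nf <- length(cell$fragments)
          for (fi in seq_len(nf)) {
            f <- cell$fragments[[fi]]
            inten <- if (!is.null(f$intensity)) f$intensity
                     else ints$red[["fragment"]] *
                       (1 + 0.3 * (fi - 1) / max(1L, nf - 1L))
            d2f <- (X - f$center[1])^2 + (Y - f$center[2])^2 + (z - f$center[3])^2
            hitf <- d2f <= f$radius^2
            red[hitf] <- inten
            tl[hitf] <- 5L
          }
        }
      }
    }
    for (ch in 1:3) {
      v <- switch(ch, red, green, blue)
      if (isTRUE(spec$noise$poisson)) v <- matrix(stats::rpois(length(v), pmax(v, 0)), ny, nx)
      if (spec$noise$gaussian_sd > 0)
        v <- v + stats::rnorm(length(v), 0, spec$noise$gaussian_sd)
      data[, , ch, k] <- pmin(pmax(as.integer(round(v)), 0L), 4095L)
    }
    truth_label[, , k] <- tl
  }

  truth <- do.call(rbind, lapply(seq_along(spec$cells), function(ci) {
    cell <- spec$cells[[ci]]
    a <- cell$semi_axes
    vn <- if (is.null(cell$nucleus_radius)) NA_real_
          else 4 / 3 * pi * cell$nucleus_radius^3
    data.frame(
      cell_id = ci,
      V_c = 4 / 3 * pi * prod(a),
      V_n = vn,
      n_fragments = if (is.null(cell$nucleus_radius)) 0L
                    else if (is.null(cell$fragments)) 1L
                    else length(cell$fragments),
      viability = if (cell$membrane) "apoptotic" else "viable",
      x = cell$center[1], y = cell$center[2], z = cell$center[3],
      CD_nc = if (is.null(cell$nucleus_radius)) NA_real_
              else sqrt(sum((cell$nucleus_center - cell$center)^2))
    )
  }))

  stack <- image_stack(data, pixel_size_xy = px, z_step_air = spec$z_step_air)
  list(stack = stack, truth = truth, truth_label = truth_label,
       mitochondria = mitos)
}

#' Analytic morphometry expectations for a phantom
#'
#' Closed-form expectations for the voxel pipeline on an ideal (noise-free,
#' perfectly segmented) phantom: exact volumes, equivalent radii and
#' centroid distances, and the face-counting limits for spherical
#' compartments (surface area `S -> 6*pi*r^2`, hence sphericity
#' `VSi -> 2/3` and `SVr * ER -> 4.5`).
#'
#' @param spec a [phantom_spec()].
#' @return `data.frame` with one row per cell.
#' @export
truth_morphometry <- function(spec) {
  do.call(rbind, lapply(seq_along(spec$cells), function(ci) {
    cell <- spec$cells[[ci]]
    a <- cell$semi_axes
    V <- 4 / 3 * pi * prod(a)
    spherical <- diff(range(a)) < 1e-9
    data.frame(
      cell_id = ci,
      V_c = V,
      ER_c = (3 * V / (4 * pi))^(1 / 3),
      S_c_limit = if (spherical) 6 * pi * a[1]^2 else NA_real_,
      VSi_limit = if (spherical) 2 / 3 else NA_real_,
      V_n = if (is.null(cell$nucleus_radius)) NA_real_
            else 4 / 3 * pi * cell$nucleus_radius^3,
      ER_n = if (is.null(cell$nucleus_radius)) NA_real_
             else cell$nucleus_radius,
      CD_nc = if (is.null(cell$nucleus_radius)) NA_real_
              else sqrt(sum((cell$nucleus_center - cell$center)^2))
    )
  }))
}

#' Sample a parametric morphometry cohort
#'
#' Draws `n` synthetic morphometry rows with each parameter independently
#' normal, using the bundled reference cohort means and SDs as the
#' generating distribution. Used for calibration studies of the two-group
#' statistics (e.g. type-I error of [compare_groups()] under a shared
#' distribution).
#'
#' @param n number of cells.
#' @param seed integer seed.
#' @param group `"viable"` or `"apoptotic"`: which reference column set to
#'   draw from.
#' @param stats reference table (default [reference_cohort_stats()]).
#' @return `data.frame` with one column per parameter symbol.
#' @export
sample_morphometry_cohort <- function(n, seed = 1L, group = c("viable", "apoptotic"),
                                      stats = reference_cohort_stats()) {
  group <- match.arg(group)
  set.seed(seed)
  mcol <- paste0("mean_", group); scol <- paste0("sd_", group)
  out <- lapply(seq_len(nrow(stats)), function(i)
    stats::rnorm(n, stats[[mcol]][i], stats[[scol]][i]))
  names(out) <- stats$symbol
  as.data.frame(out)
}
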