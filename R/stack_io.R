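# Reading and writing of confocal image stacks and reconstructed voxel
# lattices. Stacks travel as multi-page TIFF (one page per z slice, three
# 16-bit samples per pixel holding the 12-bit R/G/B channel data) with a JSON
# sidecar for acquisition metadata; lattices as a directory archive of
# meta.json plus lossless 16-bit TIFFs.

CHANNELS <- c("red", "green", "blue")
MAX_12BIT <- 4095L

#' Multi-channel confocal image stack
#'
#' Container for an ordered z-stack of three-channel 12-bit frames together
#' with its acquisition metadata. Channel identity is positional: red =
#' nuclear stain (Syto-61), green = mitochondrial stain (Mito-Tracker
#' Orange), blue = membrane stain (Annexin V).
#'
#' @param data integer array of dimension `c(ny, nx, 3, nz)` with values in
#'   `[0, 4095]`.
#' @param pixel_size_xy xy pixel size in micrometres (> 0).
#' @param z_step_air z step between acquired slices, in air, micrometres (> 0).
#' @param roi optional region of interest `c(x, y, w, h)` in 1-based pixel
#'   coordinates.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_xy, z_step_air, roi = NULL) {
  dm <- dim(data)
  if (length(dm) != 4L || dm[3L] != 3L)
    stop("`data` must be a (ny, nx, 3, nz) array", call. = FALSE)
  if (min(data) < 0 || max(data) > MAX_12BIT)
    stop("intensities must lie in [0, 4095]", call. = FALSE)
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0)
    stop("`pixel_size_xy` must be > 0", call. = FALSE)
  if (!is.numeric(z_step_air) || z_step_air <= 0)
    stop("`z_step_air` must be > 0", call. = FALSE)
  if (!is.null(roi)) roi <- validate_roi(roi, dm[1:2])
  structure(
    list(data = data, pixel_size_xy = pixel_size_xy, z_step_air = z_step_air,
         roi = roi),
    class = "image_stack"
  )
}

validate_roi <- function(roi, dm_yx) {
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(roi[3:4] < 1L))
    stop("roi must be c(x, y, w, h) with w, h >= 1", call. = FALSE)
  if (roi[1] < 1L || roi[2] < 1L ||
      roi[1] + roi[3] - 1L > dm_yx[2L] || roi[2] + roi[4] - 1L > dm_yx[1L])
    stop("roi exceeds frame bounds", call. = FALSE)
  roi
}

#' @export
print.image_stack <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf(
    "image_stack: %d x %d px, %d slices, 3 channels (12-bit)\n  pixel %g um, z step (air) %g um\n",
    dm[2], dm[1], dm[4], x$pixel_size_xy, x$z_step_air))
  invisible(x)
}

#' Number of z slices in a stack
#' @param stack an `image_stack`.
#' @export
n_slices <- function(stack) dim(stack$data)[4L]

#' Extract one channel of one slice
#'
#' @param stack an `image_stack`.
#' @param z slice index (1-based).
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return Integer intensity matrix (ny x nx).
#' @export
get_slice <- function(stack, z, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  stack$data[, , match(channel, CHANNELS), z]
}

sidecar_path <- function(path) paste0(path, ".json")

# Read multi-page TIFF data as stored integers. For multi-sample images the
# tiff package ignores `as.is` and returns normalized doubles, so those are
# scaled back by the declared bit depth of the file.
tiff_pages_int <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (is.double(p)) {
      bits <- attr(p, "bits.per.sample")
      if (is.null(bits)) bits <- 16L
      p <- round(p * (2^bits - 1))
    }
    storage.mode(p) <- "integer"
    p
  })
}

#' Write an image stack to a multi-page TIFF with JSON sidecar
#'
#' Each z slice becomes one TIFF page with three 16-bit samples per pixel;
#' the 12-bit values are stored losslessly. Acquisition metadata (pixel size,
#' air z step, ROI) goes to `<path>.json`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  dm <- dim(stack$data)
  pages <- lapply(seq_len(dm[4L]), function(z) stack$data[, , , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  meta <- list(pixel_size_xy = stack$pixel_size_xy,
               z_step_air = stack$z_step_air,
               roi = stack$roi, bit_depth = 12L, channels = CHANNELS)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-channel confocal stack
#'
#' Reads a multi-page TIFF written by [write_stack()] or any 3-sample TIFF
#' stack. Metadata is taken from the JSON sidecar `<path>.json` if present,
#' otherwise it must be supplied via `metadata`. Values are returned exactly
#' as stored; data exceeding 12 bits is an error unless `rescale = TRUE`, in
#' which case intensities are linearly mapped onto `[0, 4095]`.
#'
#' @param path TIFF file path.
#' @param metadata optional list with `pixel_size_xy`, `z_step_air` and
#'   optionally `roi`; overrides the sidecar.
#' @param rescale map >12-bit data down to the 12-bit range instead of
#'   raising a format error.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, metadata = NULL, rescale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff_pages_int(path),
                    error = function(e) stop("corrupt or unreadable TIFF: ",
                                             conditionMessage(e), call. = FALSE))
  dm1 <- dim(pages[[1L]])
  if (length(dm1) != 3L || dm1[3L] != 3L)
    stop("expected 3 channel samples per pixel", call. = FALSE)
  if (!all(vapply(pages, function(p) identical(dim(p), dm1), logical(1))))
    stop("slices do not share dimensions", call. = FALSE)
  data <- array(0L, c(dm1[1L], dm1[2L], 3L, length(pages)))
  for (z in seq_along(pages)) data[, , , z] <- as.integer(pages[[z]])
  mx <- max(data)
  if (mx > MAX_12BIT) {
    if (!rescale)
      stop(sprintf("intensity %d exceeds the 12-bit maximum 4095; pass rescale = TRUE to map down", mx),
           call. = FALSE)
    data[] <- as.integer(round(data * (MAX_12BIT / mx)))
  }
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
  if (!is.null(metadata)) meta[names(metadata)] <- metadata
  if (is.null(meta$pixel_size_xy) || is.null(meta$z_step_air))
    stop("no sidecar metadata found; supply `metadata` with pixel_size_xy and z_step_air",
         call. = FALSE)
  roi <- meta$roi
  if (!is.null(roi) && length(roi) == 0L) roi <- NULL
  image_stack(data, meta$pixel_size_xy, meta$z_step_air, roi = roi)
}

#' Reconstructed voxel lattice
#'
#' The 3D grid produced by [build_lattice()]: a per-voxel organelle label
#' (see [label_codes]) and per-channel 12-bit intensities, with physical
#' voxel sizes in micrometres. `acquired_z` records which z planes were
#' acquired (as opposed to interpolated).
#'
#' @param label integer array `(ny, nx, nz)` with values from [label_codes].
#' @param intensity integer array `(ny, nx, nz, 3)` in `[0, 4095]`
#'   (red, green, blue).
#' @param voxel_size numeric `c(dx, dy, dz)` in micrometres.
#' @param acquired_z integer indices of acquired z planes.
#' @return An object of class `voxel_lattice`.
#' @export
voxel_lattice <- function(label, intensity, voxel_size,
                          acquired_z = seq_len(dim(label)[3L])) {
  dm <- dim(label)
  stopifnot(length(dm) == 3L, identical(dim(intensity)[1:3], dm),
            dim(intensity)[4L] == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (!all(label %in% label_codes))
    stop("unknown label codes present", call. = FALSE)
  if (min(intensity) < 0 || max(intensity) > MAX_12BIT)
    stop("intensities must lie in [0, 4095]", call. = FALSE)
  structure(
    list(label = label, intensity = intensity,
         voxel_size = as.numeric(voxel_size),
         acquired_z = as.integer(acquired_z)),
    class = "voxel_lattice"
  )
}

#' @export
print.voxel_lattice <- function(x, ...) {
  dm <- dim(x$label)
  cat(sprintf(
    "voxel_lattice: %d x %d x %d voxels of %.4g x %.4g x %.4g um\n  organelle voxels: %d (%d acquired planes)\n",
    dm[2], dm[1], dm[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    sum(x$label != 0L), length(x$acquired_z)))
  invisible(x)
}

#' Write a voxel lattice archive
#'
#' Saves a lattice as a directory containing `meta.json` (dimensions, voxel
#' sizes, label code table, acquired planes) plus lossless 16-bit multi-page
#' TIFFs for the label volume and each intensity channel. Round-trips
#' bit-exactly through [read_lattice()].
#'
#' @param lattice a `voxel_lattice`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("cannot create ", path, call. = FALSE)
  dm <- dim(lattice$label)
  meta <- list(dims = dm, voxel_size = lattice$voxel_size,
               acquired_z = lattice$acquired_z,
               label_codes = as.list(label_codes), channels = CHANNELS)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = FALSE,
                       digits = NA)
  wr <- function(vol, file) {
    pages <- lapply(seq_len(dm[3L]), function(z) vol[, , z] / 65535)
    tiff::writeTIFF(pages, file.path(path, file), bits.per.sample = 16L,
                    compression = "LZW")
  }
  wr(lattice$label, "label.tif")
  for (i in 1:3) wr(lattice$intensity[, , , i], paste0(CHANNELS[i], ".tif"))
  invisible(path)
}

#' Read a voxel lattice archive
#'
#' @param path directory written by [write_lattice()].
#' @return A `voxel_lattice`.
#' @export
read_lattice <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a lattice archive: ", path, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dm <- as.integer(meta$dims)
  rd <- function(file) {
    pages <- tiff_pages_int(file.path(path, file))
    vol <- array(0L, dm)
    for (z in seq_along(pages)) vol[, , z] <- as.integer(pages[[z]])
    vol
  }
  label <- rd("label.tif")
  intensity <- array(0L, c(dm, 3L))
  for (i in 1:3) intensity[, , , i] <- rd(paste0(CHANNELS[i], ".tif"))
  voxel_lattice(label, intensity, as.numeric(meta$voxel_size),
                as.integer(meta$acquired_z))
}

#' Write a per-cell morphometry table to CSV
#'
#' @param table data frame as returned by [morphometry_table()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell morphometry table from CSV
#' @param path CSV written by [write_cell_table()].
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
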