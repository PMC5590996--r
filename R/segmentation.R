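# Per-slice threshold determination and morphological segmentation of each
# channel into organelle pixel groups.
#
# The red channel (Syto-61) is split three ways into background / cytoplasm /
# nucleus, the green channel (Mito-Tracker Orange) into background /
# cytoplasm / mitochondria, and the blue channel (Annexin V) into membrane /
# non-membrane pixels relative to the fused cell mask.

#' Histogram threshold for one slice inside a ROI
#'
#' Determines a single intensity threshold from the histogram of the pixels
#' inside the region of interest by Otsu's between-class-variance
#' maximization (at the full 12-bit resolution of 4096 levels). On a frame
#' containing background, cytoplasm and a bright organelle the maximal
#' between-class variance typically falls at the strongest gap, which is the
#' cut separating the bright organelle; [segment_slice()] derives the
#' remaining cut below it.
#'
#' A constant ROI is degenerate: the threshold equals that intensity and the
#' result carries `attr(, "degenerate") = TRUE`.
#'
#' @param slice integer intensity matrix (one channel of one z slice).
#' @param roi optional `c(x, y, w, h)` in 1-based pixel coordinates; default
#'   is the whole frame.
#' @return Threshold intensity (numeric scalar, within the ROI's intensity
#'   range), with attribute `degenerate`.
#' @export
slice_threshold <- function(slice, roi = NULL) {
  px <- roi_pixels(slice, roi)
  rng <- range(px)
  if (rng[1L] == rng[2L]) {
    th <- as.numeric(rng[1L])
    attr(th, "degenerate") <- TRUE
    return(th)
  }
  th <- otsu_threshold(px)
  attr(th, "degenerate") <- FALSE
  th
}

roi_pixels <- function(slice, roi) {
  if (is.null(roi)) return(as.vector(slice))
  roi <- validate_roi(roi, dim(slice))
  as.vector(slice[roi[2]:(roi[2] + roi[4] - 1L), roi[1]:(roi[1] + roi[3] - 1L)])
}

# Otsu threshold of a 12-bit pixel vector via EBImage, on the native 4096
# intensity levels.
otsu_threshold <- function(px) {
  img <- EBImage::Image(matrix(px / 4095, nrow = 1L))
  as.numeric(EBImage::otsu(img, range = c(0, 1), levels = 4096L)) * 4095
}

remove_small <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  counts <- tabulate(as.integer(lab))
  keep <- which(counts >= min_px)
  matrix(as.integer(lab) %in% keep, nrow = nrow(mask))
}

clean_mask <- function(mask, min_px, fill = TRUE) {
  if (!any(mask)) return(mask)
  img <- EBImage::closing(EBImage::Image(mask * 1), EBImage::makeBrush(3L, "box"))
  if (fill) img <- EBImage::fillHull(img)
  m <- matrix(as.integer(img) > 0L, nrow = nrow(mask))
  remove_small(m, min_px)
}

#' Segment one channel slice into organelle groups
#'
#' Partitions a red- or green-channel slice into background, cytoplasm and a
#' bright organelle (nucleus resp. mitochondria) using the supplied threshold
#' as the organelle cut. The cell/background cut is recovered by a second
#' Otsu pass on the sub-threshold pixels and accepted only when the two
#' resulting classes differ by at least `min_contrast` intensity units in
#' mean; otherwise the supplied threshold itself is treated as the
#' cell/background cut and the organelle cut is sought by an Otsu pass within
#' the cell mask under the same contrast guard. Masks are cleaned by a 3x3
#' closing, hole filling and removal of small components; touching nuclei are
#' separated by a watershed on the distance transform.
#'
#' @param slice integer intensity matrix.
#' @param role `"red"` (organelle = nucleus) or `"green"` (organelle =
#'   mitochondria).
#' @param threshold intensity cut from [slice_threshold()] or user-supplied.
#' @param min_contrast minimum difference of class mean intensities for a cut
#'   to be considered real (default 50).
#' @param min_component_px minimum cell-mask component size in pixels
#'   (default 20).
#' @param min_organelle_px minimum organelle component size in pixels
#'   (default 5).
#' @return A `slice_label_map`: list with `labels` (integer matrix, 0 =
#'   background, 1 = cytoplasm, 2 = organelle), `organelle_objects` (integer
#'   matrix of watershed-separated organelle instances), `role`,
#'   `threshold_used`, `threshold_low` and `flags` (character).
#' @export
segment_slice <- function(slice, role = c("red", "green"), threshold,
                          min_contrast = 50, min_component_px = 20L,
                          min_organelle_px = 5L) {
  role <- match.arg(role)
  flags <- character()
  dmy <- dim(slice)
  empty <- function(flag) {
    structure(list(labels = matrix(0L, dmy[1], dmy[2]),
                   organelle_objects = matrix(0L, dmy[1], dmy[2]),
                   role = role, threshold_used = threshold,
                   threshold_low = NA_real_, flags = flag),
              class = "slice_label_map")
  }
  if (diff(range(slice)) == 0) return(empty("constant_slice"))
  hi <- slice >= threshold
  if (!any(hi)) return(empty("all_background"))
  # a slice holding only noise has nearly equal class means on either side
  # of any cut; treat it as empty rather than welding noise into objects
  if (any(!hi) && (mean(slice[hi]) - mean(slice[!hi])) < min_contrast)
    return(empty("low_contrast"))

  lo_px <- slice[!hi]
  t_lo <- NA_real_
  org <- hi
  if (length(lo_px) > 0L && diff(range(lo_px)) > 0) {
    t_cand <- otsu_threshold(lo_px)
    m_low <- mean(lo_px[lo_px < t_cand])
    m_mid <- mean(lo_px[lo_px >= t_cand])
    if (is.finite(m_low) && is.finite(m_mid) && (m_mid - m_low) >= min_contrast) {
      # real cytoplasm class below the supplied cut
      t_lo <- t_cand
    }
  }
  if (is.na(t_lo)) {
    # supplied cut separates cell from background; look for the organelle
    # within the cell mask instead
    t_lo <- threshold
    cell <- hi
    cell_px <- slice[cell]
    org <- matrix(FALSE, dmy[1], dmy[2])
    if (diff(range(cell_px)) > 0) {
      t2 <- otsu_threshold(cell_px)
      m_below <- mean(cell_px[cell_px < t2])
      m_above <- mean(cell_px[cell_px >= t2])
      if (is.finite(m_below) && is.finite(m_above) &&
          (m_above - m_below) >= min_contrast) {
        org <- cell & (slice >= t2)
        threshold <- t2
      } else flags <- c(flags, "no_organelle_cut")
    } else flags <- c(flags, "no_organelle_cut")
  }

  cell <- clean_mask(slice >= t_lo, min_component_px, fill = TRUE)
  org <- org & cell
  org <- if (role == "red") clean_mask(org, min_organelle_px, fill = TRUE)
         else remove_small(org, min_organelle_px)
  if (!any(cell)) return(empty("all_background"))

  objects <- matrix(0L, dmy[1], dmy[2])
  if (any(org)) {
    ws <- EBImage::watershed(EBImage::distmap(EBImage::Image(org * 1)))
    objects <- matrix(as.integer(ws), nrow = dmy[1])
  }
  labels <- matrix(0L, dmy[1], dmy[2])
  labels[cell] <- 1L
  labels[org] <- 2L
  structure(list(labels = labels, organelle_objects = objects, role = role,
                 threshold_used = as.numeric(threshold),
                 threshold_low = as.numeric(t_lo), flags = flags),
            class = "slice_label_map")
}

#' @export
print.slice_label_map <- function(x, ...) {
  cat(sprintf("slice_label_map (%s): %d cytoplasm px, %d organelle px (cut %.1f)\n",
              x$role, sum(x$labels == 1L), sum(x$labels == 2L), x$threshold_used))
  invisible(x)
}

#' Membrane shell of a cell mask
#'
#' Separates blue-channel pixels into on/off cytoplasmic membrane: the
#' membrane is the shell of width `shell_px` on each side of the cell-mask
#' boundary (disc-shaped structuring element). An optional intensity cut
#' restricts the shell to pixels at or above `blue_threshold`.
#'
#' @param blue_slice blue-channel intensity matrix.
#' @param cell_mask logical matrix, the fused cell mask of the same slice.
#' @param shell_px half-width of the membrane shell in pixels (default 2).
#' @param blue_threshold optional intensity cut; `NULL` (default) keeps the
#'   purely geometric shell.
#' @return Logical matrix marking membrane pixels.
#' @export
membrane_mask <- function(blue_slice, cell_mask, shell_px = 2L,
                          blue_threshold = NULL) {
  if (!any(cell_mask)) return(cell_mask & FALSE)
  brush <- EBImage::makeBrush(2L * shell_px + 1L, "disc")
  # pad with background so a mask touching the frame edge still erodes
  # there (the frame boundary counts as outside the cell)
  n <- nrow(cell_mask); m <- ncol(cell_mask); s <- shell_px
  pad <- matrix(0, n + 2L * s, m + 2L * s)
  pad[(s + 1L):(s + n), (s + 1L):(s + m)] <- cell_mask * 1
  img <- EBImage::Image(pad)
  crop <- function(x) matrix(as.integer(x) > 0L,
                             nrow = n + 2L * s)[(s + 1L):(s + n),
                                                (s + 1L):(s + m)]
  dil <- crop(EBImage::dilate(img, brush))
  ero <- crop(EBImage::erode(img, brush))
  shell <- dil & !ero
  if (!is.null(blue_threshold)) shell <- shell & (blue_slice >= blue_threshold)
  shell
}
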