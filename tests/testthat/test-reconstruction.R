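blank_map <- function(dmn, labels) {
  structure(list(labels = labels, organelle_objects = labels * 0L,
                 role = "red", threshold_used = 0, threshold_low = 0,
                 flags = character()), class = "slice_label_map")
}

test_that("channel fusion keeps the larger cell area with a red tie-break", {
  lr <- matrix(0L, 40, 40); lr[5:34, 5:34] <- 1L   # 900 px
  lg <- matrix(0L, 40, 40); lg[3:35, 3:35] <- 1L   # 1089 px
  red <- blank_map(40L, lr); green <- blank_map(40L, lg)
  expect_identical(fuse_channels(red, green), lg > 0L)
  # tie -> red
  lg2 <- matrix(0L, 40, 40); lg2[6:35, 6:35] <- 1L # 900 px elsewhere
  expect_identical(fuse_channels(red, blank_map(40L, lg2)), lr > 0L)
  # both empty allowed
  e <- blank_map(40L, matrix(0L, 40, 40))
  expect_equal(sum(fuse_channels(e, e)), 0L)
})

test_that("refraction correction is the stated linear factor", {
  expect_equal(correct_z(0.6), 0.522)
  expect_equal(correct_z(0.5), 0.435)
  expect_equal(correct_z(0.5, factor = 1), 0.5)
  expect_error(correct_z(-0.1), "> 0")
  # linearity
  s <- c(0.31, 0.5, 0.77)
  expect_equal(correct_z(3.2 * s), 3.2 * correct_z(s))
})

test_that("slice interpolation follows the cubic-voxel insertion rule", {
  mk_stack <- function(vals, px) {
    data <- array(0L, c(8L, 8L, 3L, length(vals)))
    for (z in seq_along(vals)) data[, , , z] <- vals[z]
    image_stack(data, pixel_size_xy = px, z_step_air = 0.6)
  }
  full <- matrix(1L, 8, 8)
  maps <- function(n) lapply(seq_len(n), function(z) blank_map(8L, full))
  masks <- function(n) lapply(seq_len(n), function(z) full > 0L)

  # dx = 0.1: corrected dz 0.522 -> m = 4 inserted planes, dz = 0.1044
  st <- mk_stack(c(100L, 300L), 0.1)
  lat <- build_lattice(st, maps(2), maps(2), masks(2))
  expect_equal(dim(lat$label)[3L], 6L)
  expect_equal(lat$voxel_size[3L], 0.522 / 5)
  expect_equal(lat$acquired_z, c(1L, 6L))

  # dx equal to corrected dz -> no insertion
  st0 <- mk_stack(c(100L, 300L), 0.522)
  lat0 <- build_lattice(st0, maps(2), maps(2), masks(2))
  expect_equal(dim(lat0$label)[3L], 2L)

  # single midpoint plane interpolates linearly
  st1 <- mk_stack(c(100L, 300L), 0.26)
  lat1 <- build_lattice(st1, maps(2), maps(2), masks(2))
  expect_equal(dim(lat1$label)[3L], 3L)
  expect_true(all(lat1$intensity[, , 2L, 1L] == 200L))
})

test_that("cells are extracted as 26-connected components with truth volumes", {
  dm <- c(48L, 48L, 24L)
  centers <- list(c(12, 12, 12), c(12, 36, 12), c(36, 24, 12))
  sets <- lapply(centers, function(cen) ball_idx(dm, cen, 6))
  lat <- make_lattice(dm, list(cytoplasm = unlist(sets)))
  cells <- extract_cells(lat)
  expect_length(cells, 3L)
  v_true <- 4 / 3 * pi * 6^3
  for (cell in cells)
    expect_lt(abs(length(cell$voxels) - v_true) / v_true, 0.1)
  expect_false(any(vapply(cells, function(x) x$truncated, logical(1))))

  # empty lattice -> no cells
  expect_length(extract_cells(make_lattice(dm, list())), 0L)

  # a ball clipped by the stack top is flagged truncated
  clipped <- make_lattice(dm, list(cytoplasm = ball_idx(dm, c(24, 24, 23), 6)))
  expect_true(extract_cells(clipped)[[1L]]$truncated)
})

test_that("a diagonal voxel chain is one 26-connected cell", {
  dm <- c(10L, 10L, 10L)
  diag_idx <- vapply(1:8, function(i)
    (i - 1L) * dm[1L] * dm[2L] + (i - 1L) * dm[1L] + i, integer(1))
  lat <- make_lattice(dm, list(cytoplasm = diag_idx))
  expect_length(extract_cells(lat), 1L)
})

test_that("viability is called from membrane blue signal against background", {
  dm <- c(32L, 32L, 16L)
  cell_set <- ball_idx(dm, c(16, 16, 8), 6)
  lat <- make_lattice(dm, list(cytoplasm = cell_set), blue = 10L)
  mem <- membrane_voxels(cell_set, dm)
  lab <- lat$label; lab[mem] <- label_codes[["membrane"]]
  # bright membrane
  blue <- array(10L, dm); blue[mem] <- 1500L
  inten <- lat$intensity; inten[, , , 3L] <- blue
  lat_bright <- voxel_lattice(lab, inten, c(1, 1, 1))
  cell <- extract_cells(lat_bright)[[1L]]
  expect_equal(classify_viability(cell, lat_bright)$viability, "apoptotic")
  # membrane at background level
  lat_dim <- voxel_lattice(lab, lat$intensity, c(1, 1, 1))
  cell2 <- extract_cells(lat_dim)[[1L]]
  expect_equal(classify_viability(cell2, lat_dim)$viability, "viable")
  # no membrane voxels -> undetermined
  cell3 <- cell_record(1L, cell_set)
  expect_equal(classify_viability(cell3, lat_dim)$viability, "undetermined")
})

test_that("phantom viability labels are recovered for every cell", {
  ph <- generate_phantom(two_cell_phantom())
  res <- run_pipeline(stack = ph$stack)
  got <- res$morphometry[order(res$morphometry$CD_nc), ]
  expect_equal(sort(res$morphometry$viability), sort(ph$truth$viability))
})

test_that("cell volume is stable when the acquisition z-step is halved", {
  base <- phantom_spec(frame = c(64L, 64L), n_slices = 26L, pixel_size_xy = 0.4,
                       z_step_air = 0.5,
                       cells = list(phantom_cell(center = c(12.8, 12.8, 5.6),
                                                 radius = 4.5)),
                       noise = list(gaussian_sd = 0), seed = 9)
  fine <- phantom_spec(frame = c(64L, 64L), n_slices = 51L, pixel_size_xy = 0.4,
                       z_step_air = 0.25,
                       cells = base$cells, noise = list(gaussian_sd = 0),
                       seed = 9)
  v_of <- function(spec) {
    res <- run_pipeline(stack = generate_phantom(spec)$stack)
    res$morphometry$V_c[1L]
  }
  v1 <- v_of(base); v2 <- v_of(fine)
  expect_lt(abs(v1 - v2) / v1, 0.02)
})
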