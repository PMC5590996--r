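test_that("membrane voxels are exactly the face-exposed voxels", {
  dm <- c(24L, 24L, 24L)
  # single voxel: fully exposed
  single <- 5000L
  expect_equal(membrane_voxels(single, dm), single)
  # 3x3x3 block: all but the center voxel
  a <- as.matrix(expand.grid(10:12, 10:12, 10:12))
  block <- (a[, 3] - 1L) * dm[1] * dm[2] + (a[, 2] - 1L) * dm[1] + a[, 1]
  expect_length(membrane_voxels(block, dm), 26L)
  # digital ball: identical to a brute-force 6-neighbour scan
  ball <- ball_idx(dm, c(12, 12, 12), 8)
  inset <- array(FALSE, dm); inset[ball] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  brute <- integer()
  for (v in ball) {
    p <- arrayInd(v, dm)
    exposed <- FALSE
    for (k in seq_len(6)) {
      q <- p + offs[k, ]
      if (any(q < 1L) || any(q > dm) ||
          !inset[q[1], q[2], q[3]]) exposed <- TRUE
    }
    if (exposed) brute <- c(brute, v)
  }
  expect_setequal(membrane_voxels(ball, dm), brute)
})

test_that("digital-ball morphometry approaches the face-counting limits", {
  dm <- c(24L, 24L, 24L)
  ball <- ball_idx(dm, c(12, 12, 12), 10)
  lat <- make_lattice(dm, list(cytoplasm = ball))
  p <- compute_params(extract_cells(lat)[[1L]], lat)
  v_true <- 4 / 3 * pi * 1000
  expect_lt(abs(p$V_c - v_true) / v_true, 0.02)
  expect_lt(abs(p$ER_c - 10) / 10, 0.01)
  expect_lt(abs(p$VSi_c - 2 / 3) / (2 / 3), 0.03)
  expect_lt(abs(p$SVr_c * p$ER_c - 4.5) / 4.5, 0.05)
  # mem-to-cen distances concentrate at the radius
  expect_lt(abs(p$R_c_mean - 10) / 10, 0.05)
  expect_lt(p$R_c_std, 0.6)
})

test_that("centroid distance and volume ratios follow the construction", {
  dm <- c(32L, 32L, 32L)
  cell_set <- ball_idx(dm, c(16, 16, 16), 10)
  nuc_set <- ball_idx(dm, c(16, 19, 16), 5)  # offset 3 voxels along x
  lat <- make_lattice(dm, list(cytoplasm = setdiff(cell_set, nuc_set),
                               nucleus = nuc_set))
  p <- compute_params(extract_cells(lat)[[1L]], lat)
  expect_lt(abs(p$CD_nc - 3), 1)
  expect_lt(abs(p$Vr_nc - 5^3 / 10^3) / (5^3 / 10^3), 0.1)
})

test_that("scale law: voxel size scales V, S, GP with their dimensions", {
  dm <- c(24L, 24L, 24L)
  ball <- ball_idx(dm, c(12, 12, 12), 8)
  lat1 <- make_lattice(dm, list(cytoplasm = ball), voxel_size = c(1, 1, 1))
  lat2 <- make_lattice(dm, list(cytoplasm = ball), voxel_size = c(2, 2, 2))
  p1 <- compute_params(extract_cells(lat1)[[1L]], lat1)
  p2 <- compute_params(extract_cells(lat2)[[1L]], lat2)
  expect_equal(p2$V_c, 8 * p1$V_c)
  expect_equal(p2$S_c, 4 * p1$S_c)
  expect_equal(p2$GP_c, 2 * p1$GP_c)
  expect_equal(p2$VSi_c, p1$VSi_c)
  expect_equal(p2$SIi_c, p1$SIi_c / sqrt(2))
})

test_that("V and ER are invariant under lattice rotations of the voxel set", {
  dm <- c(26L, 26L, 26L)
  idx <- which(array(TRUE, dm))
  a <- arrayInd(idx, dm)
  ell <- idx[((a[, 1] - 13) / 9)^2 + ((a[, 2] - 13) / 6)^2 +
               ((a[, 3] - 13) / 5)^2 <= 1]
  lat <- make_lattice(dm, list(cytoplasm = ell))
  p <- compute_params(extract_cells(lat)[[1L]], lat)
  rot <- array(FALSE, dm); rot[ell] <- TRUE
  rot <- aperm(rot, c(2L, 1L, 3L))  # 90 degree rotation in the xy plane
  lat_r <- make_lattice(dm, list(cytoplasm = which(rot)))
  p_r <- compute_params(extract_cells(lat_r)[[1L]], lat_r)
  expect_equal(p_r$V_c, p$V_c)
  expect_equal(p_r$ER_c, p$ER_c)
  expect_equal(p_r$S_c, p$S_c)
})

test_that("fluorescence statistics use the population SD and normalization", {
  dm <- c(16L, 16L, 8L)
  nuc <- ball_idx(dm, c(8, 8, 4), 3)
  lat <- make_lattice(dm, list(cytoplasm = nuc))
  lab <- lat$label; lab[nuc] <- label_codes[["nucleus"]]

  red <- array(0L, dm); red[nuc] <- 1000L
  inten <- array(0L, c(dm, 3L)); inten[, , , 1L] <- red
  lat1 <- voxel_lattice(lab, inten, c(1, 1, 1))
  cell <- extract_cells(lat1)[[1L]]
  expect_equal(unname(fluorescence_stats(cell, lat1, "nucleus", "red")),
               c(1000, 0))
  expect_equal(unname(fluorescence_stats(cell, lat1, "nucleus", "red",
                                         norm = 2)), c(2000, 0))

  half <- seq_along(nuc) %% 2L == 0L
  red2 <- array(0L, dm); red2[nuc[half]] <- 500L; red2[nuc[!half]] <- 1500L
  inten2 <- inten; inten2[, , , 1L] <- red2
  lat2 <- voxel_lattice(lab, inten2, c(1, 1, 1))
  cell2 <- extract_cells(lat2)[[1L]]
  fs <- fluorescence_stats(cell2, lat2, "nucleus", "red")
  # even split -> mean 1000, population SD 500 (up to the odd voxel)
  expect_lt(abs(fs[["mean"]] - 1000), 6)
  expect_lt(abs(fs[["sd"]] - 500), 2)

  # sampling: mean of N(800, 100) draws within 3 standard errors
  set.seed(10)
  dm3 <- c(30L, 30L, 16L)
  nuc3 <- ball_idx(dm3, c(15, 15, 8), 7)
  draws <- pmin(pmax(as.integer(round(rnorm(length(nuc3), 800, 100))), 0L), 4095L)
  lab3 <- array(0L, dm3); lab3[nuc3] <- label_codes[["nucleus"]]
  int3 <- array(0L, c(dm3, 3L)); int3[, , , 1L][nuc3] <- draws
  lat3 <- voxel_lattice(lab3, int3, c(1, 1, 1))
  cell3 <- cell_record(1L, nuc3, nucleus = nuc3)
  fs3 <- fluorescence_stats(cell3, lat3, "nucleus", "red")
  expect_lt(abs(fs3[["mean"]] - 800), 3 * 100 / sqrt(length(nuc3)))
  # empty organelle -> NA
  expect_true(all(is.na(fluorescence_stats(cell3, lat3, "mitochondria",
                                           "green"))))
})

test_that("inflection counts separate smooth from lobed cross-sections", {
  # ball: convex contours count (at most) the spec bound of 2 per slice
  dm <- c(30L, 30L, 21L)
  ball <- ball_idx(dm, c(15, 15, 11), 10)
  lat <- make_lattice(dm, list(cytoplasm = ball))
  cell <- extract_cells(lat)[[1L]]
  nsi_ball <- inflection_count(cell, lat)
  expect_lte(nsi_ball, 2L * 21L)
  expect_lte(nsi_ball, 6L)  # in practice smoothed convex contours count ~0

  # prism with an 8-lobed star cross-section in every slice: 16 sign
  # changes per slice
  n <- 64L; nz <- 20L
  mask2d <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dxx <- i - n / 2; dyy <- j - n / 2
    r <- sqrt(dxx^2 + dyy^2); th <- atan2(dyy, dxx)
    if (r <= 20 + 6 * cos(8 * th)) mask2d[i, j] <- TRUE
  }
  lab <- array(0L, c(n, n, nz))
  for (z in seq_len(nz)) lab[, , z][mask2d] <- 1L
  lat_star <- voxel_lattice(lab, array(0L, c(n, n, nz)) |>
                              array(c(n, n, nz, 3L)), c(1, 1, 1))
  cell_star <- extract_cells(lat_star)[[1L]]
  nsi_star <- inflection_count(cell_star, lat_star)
  expect_equal(nsi_star, 16L * nz)

  # single-voxel-thick cell: every contour too short, count 0
  thin <- make_lattice(c(10L, 10L, 4L),
                       list(cytoplasm = c(45L, 55L)))
  cell_thin <- extract_cells(thin)[[1L]]
  expect_equal(inflection_count(cell_thin, thin), 0L)
})

test_that("empty mitochondria leave their morphometry fields absent", {
  dm <- c(24L, 24L, 12L)
  cell_set <- ball_idx(dm, c(12, 12, 6), 5)
  lat <- make_lattice(dm, list(cytoplasm = cell_set))
  p <- compute_params(extract_cells(lat)[[1L]], lat)
  expect_true(is.na(p$V_m))
  expect_true(is.na(p$Vr_mc))
  expect_true(is.na(p$GP_m))
})
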