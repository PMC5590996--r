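nuc_lattice_with_red <- function(dm, nuc, red_vals) {
  lab <- array(0L, dm); lab[nuc] <- label_codes[["nucleus"]]
  inten <- array(0L, c(dm, 3L))
  inten[, , , 1L][nuc] <- red_vals
  voxel_lattice(lab, inten, c(1, 1, 1))
}

fake_hist <- function(counts) {
  structure(list(intensity = 0:4095, counts = counts,
                 smoothed = signal::sgolayfilt(counts, p = 3L, n = 5L)),
            class = "nuclear_histogram")
}

test_that("nuclear histograms preserve counts and smooth to the right mode", {
  dm <- c(16L, 16L, 8L)
  nuc <- ball_idx(dm, c(8, 8, 4), 3)
  lat <- nuc_lattice_with_red(dm, nuc, 500L)
  cell <- cell_record(1L, nuc, nucleus = nuc)
  h <- nuclear_histogram(cell, lat)
  expect_equal(sum(h$counts), length(nuc))
  expect_equal(which(h$counts > 0) - 1L, 500L)
  expect_equal(which.max(h$smoothed) - 1L, 500L)

  # symmetric triangle of counts around 100
  n <- length(nuc)
  vals <- rep(c(99L, 100L, 101L), c(10L, 20L, 10L))
  lat2 <- nuc_lattice_with_red(dm, nuc[1:40], vals)
  h2 <- nuclear_histogram(cell_record(1L, nuc[1:40], nucleus = nuc[1:40]), lat2)
  expect_equal(which.max(h2$smoothed) - 1L, 100L)

  # mode of ~1e4 quantized N(800, 100) draws: at bin width 1 the peak
  # bins hold ~37 counts, so the smoothed argmax fluctuates by roughly
  # sqrt-law +/- 30 around 800 (simulated over seeds); 40 bounds that
  # while still catching any systematic shift of the smoother
  set.seed(12)
  dm3 <- c(40L, 40L, 40L)
  nuc3 <- ball_idx(dm3, c(20, 20, 20), 13)  # ~9200 voxels
  draws <- pmin(pmax(as.integer(round(rnorm(length(nuc3), 800, 100))), 0L), 4095L)
  lat3 <- nuc_lattice_with_red(dm3, nuc3, draws)
  h3 <- nuclear_histogram(cell_record(1L, nuc3, nucleus = nuc3), lat3)
  expect_lt(abs((which.max(h3$smoothed) - 1L) - 800), 40)
})

test_that("the threshold rule is exact on constructed histograms", {
  # midpoint branch: symmetric triangle peaked at 800 with slope 3/bin.
  # Five-point cubic smoothing reproduces the linear flanks exactly, so
  # the smoothed maximum is 34964/35 at 800 and the count reaches 5% of it
  # (49.95) at 800 + 317 where the flank value is 49, giving
  # I_th = (800 + 1117) / 2 = 958.5.
  counts <- integer(4096)
  ii <- -333:333
  counts[800 + ii + 1L] <- pmax(0L, 1000L - 3L * abs(ii))
  h <- fake_hist(counts)
  th <- determine_threshold(h)
  expect_equal(th$I_m, 800)
  expect_equal(th$I_5pct, 1117)
  expect_equal(th$I_th, 958.5)
  expect_false(th$saturated)
  smax <- max(h$smoothed)
  expect_lte(h$smoothed[th$I_5pct + 1L], 0.05 * smax)
  expect_true(all(h$smoothed[(th$I_m + 2L):th$I_5pct] > 0.05 * smax))

  # saturation branch: symmetric bump at 2000 on a plateau that stays far
  # above 5% of the maximum all the way to the 12-bit ceiling
  counts2 <- integer(4096)
  counts2[1991:4096] <- 500L
  counts2[1999:2003] <- counts2[1999:2003] + c(200L, 500L, 700L, 500L, 200L)
  th2 <- determine_threshold(fake_hist(counts2))
  expect_equal(th2$I_m, 2000)
  expect_true(th2$saturated)
  expect_equal(th2$I_th, (2000 + 4095) / 2)

  # single-bin degenerate: threshold equals the lone intensity
  counts3 <- integer(4096)
  counts3[501] <- 321L
  th3 <- determine_threshold(fake_hist(counts3))
  expect_true(th3$degenerate)
  expect_equal(th3$I_th, 500)

  # flat-zero histogram is an error
  expect_error(determine_threshold(fake_hist(integer(4096))), "no nucleus")
})

test_that("binarization applies the >= rule and flags empty valid sets", {
  dm <- c(16L, 16L, 8L)
  nuc <- ball_idx(dm, c(8, 8, 4), 3)
  vals <- rep(c(400L, 1200L), length.out = length(nuc))
  lat <- nuc_lattice_with_red(dm, nuc, vals)
  cell <- cell_record(1L, nuc, nucleus = nuc)
  valid <- binarize_nucleus(cell, lat, 1100)
  expect_setequal(valid, nuc[vals == 1200L])
  expect_setequal(binarize_nucleus(cell, lat, 0), nuc)
  expect_warning(binarize_nucleus(cell, lat, 4000), "empty valid")
})

test_that("cluster density matches brute-force lattice counting exactly", {
  # declared degenerate case
  expect_equal(cluster_density(matrix(c(3.5, 2.5, 9.5), 1), c(1, 1, 1))$rho, 1)

  # solid ball of valid voxels is nearly space-filling
  dm <- c(32L, 32L, 32L)
  ball <- ball_idx(dm, c(16, 16, 16), 8)
  co <- voxmorph:::voxel_centers(ball, dm, c(1, 1, 1))
  expect_gte(cluster_density(co, c(1, 1, 1))$rho, 0.9)

  # two separated balls treated as one cluster are sparse
  dm2 <- c(50L, 80L, 50L)
  pair <- c(ball_idx(dm2, c(25, 20, 25), 5), ball_idx(dm2, c(25, 50, 25), 5))
  d <- cluster_density(voxmorph:::voxel_centers(pair, dm2, c(1, 1, 1)),
                       c(1, 1, 1))
  expect_lt(abs(d$rho - 0.03), 0.01)
  expect_equal(d$n_sphere,
               brute_sphere_count(d$centroid, d$radius, c(1, 1, 1),
                                  r2 = d$r2))

  # random clusters in a 32^3 lattice, including anisotropic voxels:
  # the fast per-plane count equals the triple loop exactly
  set.seed(20)
  for (rep in 1:25) {
    k <- sample(3:60, 1L)
    idx <- sample(prod(dm), k)
    vs <- if (rep %% 2L == 0L) c(1, 1, 1) else c(0.4, 0.4, 0.435)
    co <- voxmorph:::voxel_centers(idx, dm, vs)
    d <- cluster_density(co, vs)
    expect_identical(d$n_sphere,
                     brute_sphere_count(d$centroid, d$radius, vs, r2 = d$r2))
    expect_lte(d$rho, 1)
  }

  # members always lie inside their own sphere, even when boundary ties
  # sit exactly at the radius (anisotropic voxel regression)
  vs_a <- c(0.4, 0.4, 0.435)
  ball_a <- ball_idx(c(32L, 32L, 32L), c(16, 16, 16), 7)
  d_a <- cluster_density(voxmorph:::voxel_centers(ball_a, c(32L, 32L, 32L),
                                                  vs_a), vs_a)
  expect_lte(d_a$rho, 1)
  # the index-space ball is slightly oblate in physical coordinates, so
  # its bounding sphere reaches past it and the density sits below 1
  expect_gte(d_a$rho, 0.8)
})

test_that("recursive division recovers constructed fragment sets", {
  vs <- c(1, 1, 1)
  # one solid ball stays one cluster
  one <- fragment_coords(fragment_layouts()[[1L]])
  expect_equal(split_clusters(one, vs, seed = 3)$n_cl, 1L)

  # two balls: root density ~0.03, daughters ~1 -> accepted, N_cl = 2
  two <- fragment_coords(fragment_layouts()[[2L]])
  res2 <- split_clusters(two, vs, seed = 3)
  expect_equal(res2$n_cl, 2L)
  expect_lt(res2$root$rho, 0.05)
  expect_gt(min(vapply(res2$leaves, function(l) l$rho, numeric(1))), 0.9)

  # leaves partition the valid set
  sizes <- vapply(res2$leaves, function(l) l$size, integer(1))
  expect_equal(sum(sizes), nrow(two))
  members <- sort(unlist(lapply(res2$leaves, function(l) l$members)))
  expect_identical(members, seq_len(nrow(two)))
})

test_that("clusters denser than 2/3 are never split", {
  vs <- c(1, 1, 1)
  set.seed(33)
  tested <- 0L
  while (tested < 30L) {
    co <- random_dense_cluster()
    if (nrow(co) < 2L) next
    d <- cluster_density(co, vs)
    if (d$rho <= 2 / 3) next
    tested <- tested + 1L
    res <- split_clusters(co, vs, seed = tested)
    expect_equal(length(res$leaves), 1L)
  }
})

test_that("cluster counts are stable across seeds for separated fragments", {
  co <- fragment_coords(fragment_layouts()[[3L]])
  ncl <- vapply(1:10, function(s)
    split_clusters(co, c(1, 1, 1), seed = s)$n_cl, integer(1))
  expect_true(all(ncl == 3L))
})

test_that("full fragmentation analysis isolates saturating chromatin bodies", {
  ph <- generate_phantom(fragmented_phantom())
  res <- run_pipeline(stack = ph$stack)
  expect_length(res$cells, 1L)
  f <- res$fragmentation[[1L]]
  expect_true(f$saturated)
  expect_equal(f$n_cl, 3L)

  # valid set vs ground-truth fragment mask on the acquired planes
  lat <- res$lattice
  cell <- res$cells[[1L]]
  th <- determine_threshold(nuclear_histogram(cell, lat))
  valid <- binarize_nucleus(cell, lat, th$I_th)
  va <- arrayInd(valid, dim(lat$label))
  keep <- va[, 3L] %in% lat$acquired_z
  vv <- paste(va[keep, 1L], va[keep, 2L], match(va[keep, 3L], lat$acquired_z))
  ta <- arrayInd(which(ph$truth_label == 5L), dim(ph$truth_label))
  tv <- paste(ta[, 1L], ta[, 2L], ta[, 3L])
  jac <- length(intersect(tv, vv)) / length(union(tv, vv))
  expect_gte(jac, 0.9)
})

test_that("an intact bright nucleus yields a single cluster end to end", {
  ph <- generate_phantom(two_cell_phantom())
  res <- run_pipeline(stack = ph$stack)
  ncl <- vapply(res$fragmentation, function(f) f$n_cl, integer(1))
  expect_true(all(ncl == 1L))
})
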