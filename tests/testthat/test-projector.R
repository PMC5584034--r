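test_that("central ray through a homogeneous cube gives mu times chord", {
  g <- make_geometry(det_rows = 3, det_cols = 3, det_pitch = 1,
                     angles_deg = c(0, 90))
  vol <- volume_template(c(50, 50, 50), 2)     # 100 mm cube
  vol$values[] <- 0.02
  p <- forward_project(vol, g)
  expect_equal(p$frames[2, 2, 1], 2.0, tolerance = 1e-12)
  expect_equal(p$frames[2, 2, 2], 2.0, tolerance = 1e-12)
})

test_that("all-zero volume projects to all-zero frames", {
  g <- tiny_geometry(4)
  p <- forward_project(volume_template(c(8, 8, 8), 10), g)
  expect_true(all(p$frames == 0))
})

test_that("Siddon matches the brute-force ray/box oracle", {
  vol <- random_volume(c(16, 16, 16), voxel_size = 4, seed = 7)
  g <- tiny_geometry(2, det_rows = 2, det_cols = 2, det_pitch = 15)
  p <- forward_project(vol, g)
  for (v in 1:2) for (r in 1:2) for (c in 1:2) {
    b <- tcgm4d:::detector_basis(g, v)
    oracle <- brute_force_line_integral(vol, b$src[, 1],
                                        detector_cell_position(g, v, r, c))
    expect_equal(p$frames[r, c, v], oracle, tolerance = 1e-10)
  }
})

test_that("intersection lengths of a crossing ray sum to the chord length", {
  vol <- volume_template(c(20, 20, 20), 5)     # 100 mm cube
  vol$values[] <- 1                            # line integral == path length
  g <- make_geometry(det_rows = 5, det_cols = 5, det_pitch = 30,
                     angles_deg = c(0, 33.5))
  p <- forward_project(vol, g)
  for (v in 1:2) for (r in 1:5) for (c in 1:5) {
    b <- tcgm4d:::detector_basis(g, v)
    src <- b$src[, 1]
    dst <- detector_cell_position(g, v, r, c)
    chord <- brute_force_line_integral(vol, src, dst)
    expect_equal(p$frames[r, c, v], chord, tolerance = 1e-9 * max(chord, 1))
  }
})

test_that("forward projection is linear", {
  g <- tiny_geometry(4)
  v1 <- random_volume(c(12, 12, 12), 6, seed = 1)
  v2 <- random_volume(c(12, 12, 12), 6, seed = 2)
  comb <- v1; comb$values <- 2 * v1$values + 3 * v2$values
  p <- forward_project(comb, g)$frames
  p12 <- 2 * forward_project(v1, g)$frames + 3 * forward_project(v2, g)$frames
  expect_equal(p, p12, tolerance = 1e-12)
})

test_that("back projection is the exact adjoint for S and M FOV presets", {
  for (offset in c(0, 115)) {
    g <- tiny_geometry(16, det_rows = 16, det_cols = 16, det_pitch = 20,
                       det_offset = offset)
    vol <- volume_template(c(32, 32, 32), 4)
    set.seed(42 + offset)
    x <- array(runif(32^3), c(32, 32, 32))
    y <- array(runif(16 * 16 * 16), c(16, 16, 16))
    vx <- vol; vx$values <- x
    Ax <- forward_project(vx, g)$frames
    ps <- projection_set(y, g$angles_deg, g$times_s)
    Aty <- back_project(ps, g, vol)$values
    lhs <- sum(Ax * y); rhs <- sum(x * Aty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("backprojecting a single detector element fills only its ray", {
  g <- tiny_geometry(1, det_rows = 3, det_cols = 3, det_pitch = 2)
  vol <- volume_template(c(10, 10, 10), 10)
  y <- array(0, c(3, 3, 1)); y[2, 2, 1] <- 1
  ps <- projection_set(y, g$angles_deg, g$times_s)
  bp <- back_project(ps, g, vol)$values
  # central axial ray at angle 0 runs along y through the grid center
  hit <- which(bp != 0, arr.ind = TRUE)
  expect_true(all(hit[, 1] %in% 5:6 & hit[, 3] %in% 5:6))
  # values equal per-voxel path lengths: a straight axial ray crosses each
  # voxel over its full 10 mm extent, 10 voxels for a 100 mm chord
  expect_equal(unname(bp[bp != 0]), rep(10, 10), tolerance = 1e-9)
  # zero projections backproject to zero
  ps0 <- projection_set(array(0, c(3, 3, 1)), g$angles_deg, g$times_s)
  expect_true(all(back_project(ps0, g, vol)$values == 0))
})

test_that("count transform follows n = n0 exp(-y)", {
  g <- tiny_geometry(1, det_rows = 2, det_cols = 2, det_pitch = 5)
  y <- array(c(0, log(2), 1, 2), c(2, 2, 1))
  ps <- projection_set(y, g$angles_deg, g$times_s, n0 = 1000)
  n <- counts_from_line_integrals(ps)
  expect_equal(n[1, 1, 1], 1000)         # y = 0 -> n0
  expect_equal(n[2, 1, 1], 500)          # y = ln 2, n0 = 1000
  expect_error(counts_from_line_integrals(array(-1, c(1, 1, 1)), n0 = 10),
               "negative")
})

test_that("noisy counts are Poisson with the right mean and reproducible", {
  y <- array(1, c(100, 100, 1))
  n1 <- counts_from_line_integrals(y, n0 = 1e5, noisy = TRUE, seed = 3)
  n2 <- counts_from_line_integrals(y, n0 = 1e5, noisy = TRUE, seed = 3)
  expect_identical(n1, n2)
  mu <- 1e5 * exp(-1)
  # sample mean over 1e4 draws within 3 sigma of the Poisson mean
  expect_lt(abs(mean(n1) - mu), 3 * sqrt(mu / length(n1)))
})
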