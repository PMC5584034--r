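test_that("geometry construction derives timestamps and validates inputs", {
  g <- make_geometry(angles_deg = seq(0, 359, by = 1))
  expect_length(g$times_s, 360)
  expect_equal(diff(g$times_s), rep(1 / 6, 359))  # 1 deg steps at 6 deg/s

  expect_equal(geometry_preset("full", fov = "M")$det_offset, 115)
  expect_equal(geometry_preset("full", fov = "S")$det_offset, 0)

  expect_error(make_geometry(sad = 1000, sdd = 1000, angles_deg = 0:10),
               "sdd")
  expect_error(make_geometry(angles_deg = 0:2, times_s = c(0, 2, 1)),
               "increasing")
  expect_error(make_geometry(angles_deg = 0:2, times_s = c(0, 1)),
               "length")
})

test_that("sphere motion is linear in time and clamped outside the interval", {
  sp60 <- phantom_preset("60s", "mini")
  expect_equal(sphere_center_z(sp60, 0), -15)
  expect_equal(sphere_center_z(sp60, 30), 0)
  expect_equal(sphere_center_z(sp60, 60), 15)
  expect_equal(sphere_center_z(sp60, -5), -15)   # clamped before start
  expect_equal(sphere_center_z(sp60, 75), 15)    # clamped after end

  # 3 cm/30 s: motion runs from the 90 to the 270 degree source position,
  # i.e. t = 15..45 s; the sphere is still at the start before that
  sp30 <- phantom_preset("30s", "mini")
  expect_equal(sphere_center_z(sp30, 10), -15)
  expect_equal(sphere_center_z(sp30, 30), 0)     # midpoint: displaced 15 mm
  expect_equal(sphere_center_z(sp30, 50), 15)
})

test_that("voxelized sphere volume matches (4/3) pi R^3 at 1 mm voxels", {
  sp <- phantom_spec(voxel_size = 1, grid_dims = c(48, 48, 48),
                     motion_extent = 0.001)
  vol <- phantom_volume(sp, 0)
  n_sphere <- sum(vol$values == sp$sphere_mu & abs(vol$values - sp$body_mu) > 0)
  r <- sp$sphere_diameter / 2
  analytic <- 4 / 3 * pi * r^3
  shell <- 4 * pi * r^2 * 1            # one voxel-shell tolerance
  expect_lt(abs(n_sphere - analytic), shell)
})

test_that("phantom volumes at two times differ only by an axial shift", {
  sp <- phantom_preset("60s", "mini")
  dz <- sp$voxel_size[3]
  # choose a time step moving the sphere by exactly 2 voxels (0.5 mm/s)
  dt <- 2 * dz / 0.5
  v1 <- phantom_volume(sp, 20)
  v2 <- phantom_volume(sp, 20 + dt)
  n <- dim(v1$values)[3]
  expect_equal(v2$values[, , 3:n], v1$values[, , 1:(n - 2)])
})

test_that("phantom spec validation rejects impossible configurations", {
  expect_error(phantom_spec(sphere_diameter = 200), "sphere outside")
  expect_error(phantom_spec(motion_extent = 40, cylinder_length = 60),
               "sphere outside")
  expect_error(phantom_spec(body_mu = 0), "body_mu")
  expect_error(phantom_spec(motion_start_time = 10, motion_end_time = 10),
               "motion_end_time")
})

test_that("occupancy oracle gives the closed-form 10-90% widths", {
  w <- function(extent) {
    sp <- phantom_spec(motion_extent = extent,
                       motion_start_time = 0, motion_end_time = 60)
    occupancy_edge_oracle(sp)
  }
  expect_equal(w(30)$width_mm, 24)     # 0.8 * L at L = 30, R = 15
  expect_equal(w(15)$width_mm, 12)
  sp0 <- phantom_spec(motion_extent = 0.001)
  sp0$motion_extent <- 0               # static limit: step edge
  expect_equal(occupancy_edge_oracle(sp0)$width_mm, 0)
})

test_that("oracle width is linear in the motion extent (L <= 2R)", {
  widths <- vapply(c(6, 18, 27), function(L) {
    sp <- phantom_spec(motion_extent = L)
    occupancy_edge_oracle(sp)$width_mm
  }, 1)
  expect_equal(widths, 0.8 * c(6, 18, 27))
})

test_that("oracle profile is a unit-peak trapezoid consistent with its width", {
  sp <- phantom_spec(motion_extent = 30)
  o <- occupancy_edge_oracle(sp)
  expect_equal(max(o$profile$occupancy), 1)
  # measure the 10-90% width of the sampled profile with the evaluation code
  prof <- data.frame(z = o$profile$z, value = 1 - o$profile$occupancy)
  pw <- penumbral_width(prof, background_mu = 1)
  expect_equal(pw$width_mm, o$width_mm, tolerance = 0.02)
})
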