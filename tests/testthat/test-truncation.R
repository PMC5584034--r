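# Offset-detector (M FOV) truncation and the 3-step projection extension,
# exercised at the mini scale.
trunc_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- geometry_preset("mini", fov = "M")
      sp <- phantom_preset("60s", "mini")
      sp$motion_extent <- 0.001
      grid <- volume_template(sp$grid_dims, sp$voxel_size)
      proj <- simulate_phantom_scan(g, sp)
      cache <<- list(g = g, sp = sp, grid = grid, proj = proj,
                     truth = phantom_volume(sp, 0, grid))
    }
    cache
  }
})

test_that("extended geometry defaults to 800 columns for a 512-column panel", {
  g512 <- geometry_preset("full", fov = "M")
  ext <- extended_geometry(g512)
  expect_equal(ext$geometry$det_cols, 800L)
  # measured cell centers stay on the widened lattice
  shift_u <- g512$det_offset - ext$geometry$det_offset
  expect_equal(shift_u / g512$det_pitch +
                 (ext$geometry$det_cols - g512$det_cols) / 2,
               ext$col_shift)
  expect_equal(ext$col_shift %% 1, 0)
  expect_error(extended_geometry(g512, extended_cols = 100), "must be >=")
})

test_that("extension passes untruncated S-FOV data through unchanged", {
  g <- geometry_preset("mini", fov = "S")
  sp <- phantom_preset("60s", "mini")
  sp$motion_extent <- 0.001
  grid <- volume_template(sp$grid_dims, sp$voxel_size)
  proj <- simulate_phantom_scan(g, sp)
  ext <- extend_projections(proj, g, grid, extended_cols = 168)
  k <- ext$col_shift
  expect_identical(ext$projections$frames[, (k + 1):(k + g$det_cols), ],
                   proj$frames)
})

test_that("extension restores truncated projections and lowers interior RMSE", {
  tc <- trunc_case()
  ext <- extend_projections(tc$proj, tc$g, tc$grid, extended_cols = 168)
  expect_equal(dim(ext$projections$frames)[2], 168L)
  # measured columns are kept exactly; everything is nonnegative
  k <- ext$col_shift
  expect_identical(ext$projections$frames[, (k + 1):(k + tc$g$det_cols), ],
                   tc$proj$frames)
  expect_gte(min(ext$projections$frames), 0)

  zp <- zero_pad_projections(tc$proj, tc$g, extended_cols = 168)
  fdk_ext <- reconstruct_fdk(ext$projections, ext$geometry, tc$grid,
                             redundancy = "offset")
  fdk_zp <- reconstruct_fdk(zp$projections, zp$geometry, tc$grid,
                            redundancy = "offset")
  # RMSE vs ground truth inside a central 10 cm cylinder
  x <- grid_axis(tc$grid, 1); y <- grid_axis(tc$grid, 2)
  z <- grid_axis(tc$grid, 3)
  mask <- array(FALSE, dim(tc$grid$values))
  r2 <- outer(x^2, y^2, `+`)
  for (kk in which(abs(z) < 25)) mask[, , kk] <- r2 <= 50^2
  rmse <- function(v) sqrt(mean((v$values[mask] - tc$truth$values[mask])^2))
  expect_lt(rmse(fdk_ext), rmse(fdk_zp))
})

test_that("extension requires full angular coverage", {
  tc <- trunc_case()
  half <- tc$proj
  half$frames <- half$frames[, , 1:45, drop = FALSE]
  half$angles_deg <- half$angles_deg[1:45]
  half$times_s <- half$times_s[1:45]
  g2 <- tc$g
  g2$angles_deg <- g2$angles_deg[1:45]; g2$times_s <- g2$times_s[1:45]
  expect_error(extend_projections(half, g2, tc$grid, extended_cols = 168),
               "360")
})
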