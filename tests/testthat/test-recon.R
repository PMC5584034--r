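# single-voxel, single-ray toy: grid of one 1 mm voxel on the axis, one
# detector cell on the central ray, so y = mu * 1 mm
toy_problem <- function(y_meas, n0 = 100) {
  g <- make_geometry(det_rows = 1, det_cols = 1, det_pitch = 1,
                     angles_deg = 0)
  proj <- projection_set(array(y_meas, c(1, 1, 1)), 0, 0, n0 = n0)
  grid <- volume_template(c(1, 1, 1), 1)
  list(geometry = g, projections = proj, grid = grid)
}

test_that("single-element data term is minimized at mu = ln 2", {
  # n0 = 100, n = 50: d/dy (n y + n0 e^-y) = 0 at y = ln(n0/n) = ln 2
  toy <- toy_problem(log(2))
  bin <- assign_phases(toy$projections, 1, 1)
  init <- toy$grid; init$values[] <- 0.1
  cfg <- recon_config(alpha = 0, lambda = 0, n_iterations = 60)
  res <- reconstruct_iterative(toy$projections, bin, toy$geometry, cfg,
                               initial = list(init))
  expect_equal(res$phases[[1]]$values[1, 1, 1], log(2), tolerance = 1e-6)
  expect_true(all(diff(attr(res, "objective")) <= 1e-9))
})

test_that("data term value and analytic gradient match the definition", {
  toy <- toy_problem(log(2), n0 = 100)
  vol <- toy$grid; vol$values[] <- 0.3
  r <- neg_log_likelihood(vol, toy$projections, toy$geometry, gradient = TRUE)
  expect_equal(r$value, 50 * 0.3 + 100 * exp(-0.3))
  expect_equal(r$gradient[1, 1, 1], 50 - 100 * exp(-0.3))
})

test_that("data-term gradient vanishes at the noiseless ground truth", {
  g <- tiny_geometry(4, det_rows = 8, det_cols = 8, det_pitch = 30)
  vol <- random_volume(c(8, 8, 8), 12, seed = 21)
  vol$values <- vol$values * 0.01
  y <- forward_project(vol, g, n0 = 1e4)
  r <- neg_log_likelihood(vol, y, g, gradient = TRUE)
  # relative to the gradient scale of a perturbed volume
  off <- vol; off$values <- vol$values * 1.05
  r_off <- neg_log_likelihood(off, y, g, gradient = TRUE)
  expect_lt(max(abs(r$gradient)) / max(abs(r_off$gradient)), 1e-6)
})

test_that("objective gradient matches finite differences for all presets", {
  g <- tiny_geometry(4, det_rows = 6, det_cols = 6, det_pitch = 40)
  set.seed(22)
  dims <- c(8, 8, 8)
  truth <- volume_image(array(0.01 * runif(prod(dims)), dims), 12)
  proj <- forward_project(truth, g, n0 = 1e3)
  bin <- assign_phases(proj, 2, 200)
  series <- lapply(1:2, function(i)
    volume_image(array(0.01 * runif(prod(dims)), dims), 12))
  prior <- volume_image(array(0.01 * runif(prod(dims)), dims), 12)
  idx <- c(1, 100, 256, 400, 512)
  for (method in c("tvcs", "piccs", "tcgm")) {
    cfg <- recon_preset(method, n0 = 1e3, epsilon = 1e-6)
    for (t in 1:2) {
      r <- map_objective(series, t, proj, bin, g, cfg, prior = prior,
                         lambda = 5)
      f <- function(x) {
        s <- series
        s[[t]] <- volume_image(array(x, dims), 12)
        map_objective(s, t, proj, bin, g, cfg, prior = prior, lambda = 5)$value
      }
      fd <- fd_gradient(f, as.numeric(series[[t]]$values), idx, h = 1e-6)
      expect_equal(as.numeric(r$gradient)[idx], fd, tolerance = 1e-4,
                   label = sprintf("%s gradient (phase %d)", method, t))
    }
  }
})

test_that("iterative reconstruction is monotone, nonnegative, deterministic", {
  g <- tiny_geometry(12, det_rows = 10, det_cols = 10, det_pitch = 30)
  sp <- phantom_spec(ellipse_semi_axis_x = 60, ellipse_semi_axis_y = 50,
                     sphere_diameter = 24, motion_extent = 24,
                     voxel_size = 12, grid_dims = c(12, 12, 12))
  proj <- simulate_phantom_scan(g, sp)
  bin <- assign_phases(proj, 3, 120)
  init <- rep(list(reconstruct_fdk(proj, g,
                                   volume_template(c(12, 12, 12), 12))), 3)
  for (method in c("tvcs", "tcgm")) {
    cfg <- recon_preset(method, n_iterations = 6)
    r1 <- reconstruct_iterative(proj, bin, g, cfg, initial = init)
    o <- attr(r1, "objective")
    expect_true(all(diff(o) <= 1e-9 * (1 + abs(o[-length(o)]))),
                label = paste(method, "objective monotone"))
    expect_true(all(vapply(r1$phases, function(p) min(p$values), 1) >= 0))
    r2 <- reconstruct_iterative(proj, bin, g, cfg, initial = init)
    expect_identical(r1$phases, r2$phases)
  }
})

test_that("TVCS beats FDK on noiseless static-phantom data", {
  g <- tiny_geometry(24, det_rows = 12, det_cols = 24, det_pitch = 20)
  sp <- phantom_spec(ellipse_semi_axis_x = 80, ellipse_semi_axis_y = 60,
                     sphere_diameter = 30, motion_extent = 0.001,
                     voxel_size = c(10, 10, 8), grid_dims = c(20, 20, 12))
  proj <- simulate_phantom_scan(g, sp)
  truth <- phantom_volume(sp, 0)
  grid <- volume_template(sp$grid_dims, sp$voxel_size)
  fdk <- reconstruct_fdk(proj, g, grid)
  bin <- assign_phases(proj, 1, 360)
  cfg <- recon_preset("tvcs", n_iterations = 12)
  tvcs <- reconstruct_iterative(proj, bin, g, cfg, initial = list(fdk))
  rmse <- function(v) sqrt(mean((v$values - truth$values)^2))
  expect_lt(rmse(tvcs$phases[[1]]), rmse(fdk))
})

test_that("TCGM with identical windows and static truth is phase-symmetric", {
  g <- tiny_geometry(12, det_rows = 8, det_cols = 12, det_pitch = 30)
  sp <- phantom_spec(ellipse_semi_axis_x = 60, ellipse_semi_axis_y = 50,
                     sphere_diameter = 20, motion_extent = 0.001,
                     voxel_size = 12, grid_dims = c(12, 12, 8))
  proj <- simulate_phantom_scan(g, sp)
  bin <- assign_phases(proj, 2, 180)
  bin$windows[[2]] <- bin$windows[[1]]       # identical data for both phases
  bin$center_angles[2] <- bin$center_angles[1]
  grid <- volume_template(c(12, 12, 8), 12)
  fdk <- reconstruct_fdk(proj, g, grid)
  cfg <- recon_preset("tcgm", n_iterations = 400)
  r <- reconstruct_iterative(proj, bin, g, cfg, initial = rep(list(fdk), 2))
  expect_lt(max(abs(r$phases[[1]]$values - r$phases[[2]]$values)),
            1e-3 * sp$body_mu)
})

test_that("configuration errors are caught", {
  toy <- toy_problem(0.5)
  bin <- assign_phases(toy$projections, 1, 1)
  init <- list(toy$grid)
  expect_error(reconstruct_iterative(toy$projections, bin, toy$geometry,
                                     recon_preset("piccs"), initial = init),
               "prior")
  expect_error(recon_config(alpha = -1), "weights")
  expect_error(recon_config(epsilon = 0), "epsilon")
  expect_error(reconstruct_iterative(toy$projections, bin, toy$geometry,
                                     recon_config(), initial = list()),
               "match")
})
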