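# Shared small fixtures, built in code.

# tiny geometry: few detector cells, few views
tiny_geometry <- function(n_angles = 8, det_rows = 16, det_cols = 16,
                          det_pitch = 20, det_offset = 0) {
  make_geometry(sad = 1000, sdd = 1536, det_rows = det_rows,
                det_cols = det_cols, det_pitch = det_pitch,
                det_offset = det_offset,
                angles_deg = seq(0, 360 - 360 / n_angles, by = 360 / n_angles))
}

random_volume <- function(dims, voxel_size = 4, seed = 1) {
  set.seed(seed)
  volume_image(array(runif(prod(dims)), dims), voxel_size)
}

# brute-force ray/box line integral: per-voxel slab intersection, O(V) per ray
brute_force_line_integral <- function(volume, src, dst) {
  d <- dim(volume$values)
  vx <- volume$voxel_size
  dir <- dst - src
  len <- sqrt(sum(dir^2))
  total <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    lo <- volume$origin + (c(i, j, k) - 1) * vx
    hi <- lo + vx
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (a in 1:3) {
      if (dir[a] == 0) {
        # half-open cell [lo, hi): a ray on a face belongs to the upper cell
        if (src[a] < lo[a] || src[a] >= hi[a]) { ok <- FALSE; break }
      } else {
        ta <- (lo[a] - src[a]) / dir[a]
        tb <- (hi[a] - src[a]) / dir[a]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
      }
    }
    if (ok && t1 > t0)
      total <- total + volume$values[i, j, k] * (t1 - t0) * len
  }
  total
}

# detector cell center position (1-based r, c) for a given view
detector_cell_position <- function(geometry, view, r, c) {
  b <- tcgm4d:::detector_basis(geometry, view)
  b$det0[, 1] + (c - 1) * b$eu[, 1] + (r - 1) * b$ev[, 1]
}

# numeric central-difference gradient of f at x (on a subset of coordinates)
fd_gradient <- function(f, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 1)
}
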