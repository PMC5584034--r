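# brute-force TV: explicit per-voxel summation, independent of the
# vectorized implementation
tv_brute <- function(a, eps) {
  d <- dim(a)
  at <- function(i, j, k) {
    if (i > d[1] || j > d[2] || k > d[3]) NA else a[i, j, k]
  }
  total <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dx <- if (i < d[1]) a[i, j, k] - a[i + 1, j, k] else 0
    dy <- if (j < d[2]) a[i, j, k] - a[i, j + 1, k] else 0
    dz <- if (k < d[3]) a[i, j, k] - a[i, j, k + 1] else 0
    total <- total + sqrt(dx^2 + dy^2 + dz^2 + eps)
  }
  total
}

test_that("TV of a constant volume is N sqrt(eps)", {
  a <- array(0.7, c(4, 5, 6))
  eps <- 1e-6
  expect_equal(tv_norm(a, eps), prod(dim(a)) * sqrt(eps))
})

test_that("TV of a unit step in a 2-voxel volume is 1", {
  a <- array(c(1, 0), c(2, 1, 1))
  expect_equal(tv_norm(a, 0), 1)    # first voxel contributes the step,
})                                  # the last contributes 0

test_that("TV matches the brute-force per-voxel summation", {
  set.seed(11)
  a <- array(rnorm(216), c(6, 6, 6))
  expect_equal(tv_norm(a, 1e-8), tv_brute(a, 1e-8), tolerance = 1e-12)
})

test_that("TV gradient matches central finite differences", {
  set.seed(12)
  a <- array(rnorm(60), c(5, 4, 3))
  g <- tv_norm(a, 1e-4, gradient = TRUE)$gradient
  idx <- c(1, 7, 23, 34, 60)
  fd <- fd_gradient(function(x) tv_norm(array(x, dim(a)), 1e-4),
                    as.numeric(a), idx)
  expect_equal(as.numeric(g)[idx], fd, tolerance = 1e-5)
})

test_that("PIC term is the TV of the difference image", {
  set.seed(13)
  a <- array(rnorm(64), c(4, 4, 4))
  p <- array(rnorm(64), c(4, 4, 4))
  eps <- 1e-8
  expect_equal(pic_term(a, p, eps), tv_norm(a - p, eps))
  # minimum at mu = prior; zero prior reduces to plain TV
  expect_equal(pic_term(p, p, eps), 64 * sqrt(eps))
  expect_equal(pic_term(a, array(0, dim(a)), eps), tv_norm(a, eps))
  expect_error(pic_term(a, array(0, c(2, 2, 2)), eps), "mismatch")
})

test_that("TCGM term couples a phase to its neighbours, doubled at the ends", {
  eps <- 1e-8
  n <- 4 * 4 * 4
  set.seed(14)
  mk <- function(x) volume_image(x, 1)
  a <- array(runif(n), c(4, 4, 4))
  b <- array(runif(n), c(4, 4, 4))
  cc <- array(runif(n), c(4, 4, 4))
  series <- list(mk(a), mk(b), mk(cc))
  # interior phase: sum of two independently computed TV norms
  expect_equal(tcgm_term(series, 2, eps),
               tv_norm(b - a, eps) + tv_norm(b - cc, eps))
  # identical neighbours: minimum value 2 N sqrt(eps)
  expect_equal(tcgm_term(list(mk(a), mk(a), mk(a)), 2, eps), 2 * n * sqrt(eps))
  # boundary doubling: t = 1 with mu1 = mu2
  expect_equal(tcgm_term(list(mk(a), mk(a)), 1, eps), 2 * n * sqrt(eps))
  expect_equal(tcgm_term(series, 1, eps), 2 * tv_norm(a - b, eps))
  expect_equal(tcgm_term(series, 3, eps), 2 * tv_norm(cc - b, eps))
  expect_error(tcgm_term(list(mk(a)), 1, eps), "two phases")
})

test_that("TCGM gradient matches finite differences at interior and ends", {
  eps <- 1e-4
  set.seed(15)
  dims <- c(3, 3, 3)
  series <- lapply(1:3, function(i) array(rnorm(27), dims))
  for (t in 1:3) {
    g <- tcgm_term(series, t, eps, gradient = TRUE)$gradient
    f <- function(x) {
      s <- series; s[[t]] <- array(x, dims)
      tcgm_term(s, t, eps)
    }
    idx <- c(1, 5, 14, 27)
    expect_equal(as.numeric(g)[idx],
                 fd_gradient(f, as.numeric(series[[t]]), idx),
                 tolerance = 1e-5)
  }
})
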