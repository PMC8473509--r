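# OSEM engine correctness against brute-force EM, scatter estimation,
# Gaussian filtering.

test_that("fwhm/sigma conversion matches its closed form", {
  expect_equal(fwhm_to_sigma(2.3548), 1.0, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(0), 0)
  expect_equal(fwhm_to_sigma(6.99), 2.968, tolerance = 1e-3)
  expect_error(fwhm_to_sigma(-1), "nonnegative")
})

test_that("dual-energy-window estimate applies k and the width ratio", {
  expect_true(all(dew_scatter_estimate(array(0, c(3, 3)))$values == 0))
  expect_equal(dew_scatter_estimate(100, k = 0.5, 12, 12)$values, 50)
  expect_equal(dew_scatter_estimate(100, k = 0.5, 21, 12)$values, 87.5)
  expect_error(dew_scatter_estimate(100, 0.5, 21, 0), "widths")
  expect_error(dew_scatter_estimate(-1), "nonnegative")
})

test_that("OSEM with one subset reproduces brute-force MLEM bitwise", {
  set.seed(21)
  A <- matrix(runif(12 * 8, 0.1, 1), 12, 8)
  x_true <- runif(8, 0.5, 2)
  y <- as.vector(A %*% x_true)
  x0 <- rep(1, 8)
  fit <- run_mlem_dense(A, y, x0, 15)
  xo <- x0
  for (i in 1:15) xo <- em_oracle_step(xo, A, y)
  expect_identical(fit$x, xo)
})

test_that("a 2x2 system follows the brute-force EM trajectory to 1e-8", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  y <- c(5, 3)
  x0 <- c(1, 1)
  fit <- run_mlem_dense(A, y, x0, 200)
  xo <- x0
  for (i in 1:200) xo <- em_oracle_step(xo, A, y)
  expect_equal(fit$x, xo, tolerance = 1e-8)
  # at the fixed point the model reproduces the data
  expect_equal(as.vector(A %*% fit$x), y, tolerance = 1e-6)
})

test_that("MLEM log-likelihood is non-decreasing on a 16x16 toy system", {
  set.seed(33)
  A <- matrix(runif(16 * 16, 0, 1), 16, 16)
  x_true <- runif(16, 0.2, 3)
  y <- rpois(16, as.vector(A %*% x_true))
  fit <- run_mlem_dense(A, y, rep(1, 16), 60, record = 1:60)
  ll <- vapply(fit$iterates, function(x) {
    spectrc:::poisson_loglik(y, as.vector(A %*% x))
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-9))
  expect_true(all(fit$x >= 0))
})

test_that("counts are conserved at MLEM convergence on noiseless data", {
  set.seed(5)
  A <- matrix(runif(10 * 6, 0.1, 1), 10, 6)
  y <- as.vector(A %*% runif(6, 0.5, 2))
  fit <- run_mlem_dense(A, y, rep(1, 6), 500)
  expect_equal(sum(A %*% fit$x), sum(y), tolerance = 0.005)
})

test_that("OSEM subset partition is spread and nearly equal", {
  subs <- spectrc:::subset_views(60, 7)
  expect_length(subs, 7)
  sizes <- lengths(subs)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(unlist(subs), 1:60)
  expect_error(spectrc:::subset_views(4, 5), "more subsets")
})

test_that("geometric OSEM recovers a matched-model phantom", {
  # no PSF in data or model: the system is well conditioned and MLEM
  # converges to the true concentrations quickly
  ph <- desk_phantom()
  w <- energy_window(15, scatter_fraction = 1e-9)
  cfg <- acquisition_config(n_views = 30, window = w, seed = 2)
  prim <- forward_project(ph, cfg, with_psf = FALSE)
  ps <- structure(list(photopeak = prim, scatterwin = prim * 0,
                       truth = prim, view_angles = cfg$view_angles,
                       config = cfg, phantom_spec = ph$spec, noise = FALSE),
                  class = "projection_set")
  vol <- osem_reconstruct(ps, ph$mu,
                          recon_config(iterations = 8, subsets = 10,
                                       corrections = "AC"))
  expect_true(all(vol$values >= 0))
  q <- quantify(vol, ph)
  expect_equal(q$rc[q$sphere_mm == 37], 100, tolerance = 0.10)
  expect_gt(min(q$rc), 50)
})

test_that("the Gaussian post-filter preserves mass and has the right width", {
  g <- c(41, 41, 21)
  vox <- c(2, 2, 2)
  delta <- array(0, g); delta[21, 21, 11] <- 1
  f <- 8
  sm <- gaussian_postfilter(delta, f, voxel = vox)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  prof <- sm[, 21, 11]
  half <- max(prof) / 2
  width_vox <- sum(prof >= half)
  expect_lt(abs(width_vox * vox[1] - f), 2 * vox[1])
  u <- array(3.7, g)
  su <- gaussian_postfilter(u, 4, voxel = vox)
  interior <- su[10:30, 10:30, 8:14]
  expect_equal(max(abs(interior - 3.7)), 0, tolerance = 1e-10)
  expect_error(gaussian_postfilter(u, 0, voxel = vox), "fwhm")
})
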