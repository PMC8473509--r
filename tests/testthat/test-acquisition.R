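# Acquisition physics: window model, projector conservation, Beer-Lambert
# attenuation, scatter scaling, Poisson noise and time rebinning.

test_that("window efficiency matches the closed-form Gaussian integral", {
  w15 <- energy_window(15)
  sigma <- (0.06 * 140) / (2 * sqrt(2 * log(2)))
  closed <- 2 * pnorm(10.5 / sigma) - 1          # 140 +/- 10.5 keV
  expect_equal(window_efficiency(w15), closed, tolerance = 1e-12)
  expect_equal(window_efficiency(w15), 0.9967, tolerance = 1e-3)
  # limiting windows
  wide <- energy_window(15); wide$photopeak_halfwidth_frac <- 0.999
  expect_equal(window_efficiency(wide), 1.0, tolerance = 1e-10)
  narrow <- energy_window(15); narrow$photopeak_halfwidth_frac <- 1e-9
  expect_equal(window_efficiency(narrow), 0.0, tolerance = 1e-6)
  # primary photons barely reach the lower scatter window
  expect_lt(window_efficiency(w15, "scatter"), 1e-3)
})

test_that("the 20% window accepts more primaries and more scatter", {
  w15 <- energy_window(15)
  w20 <- energy_window(20)
  expect_gte(window_efficiency(w20), window_efficiency(w15))
  expect_gt(w20$scatter_fraction, w15$scatter_fraction)
  expect_equal(w15$photopeak_width_kev, 21)
  expect_equal(w15$scatter_width_kev, 12)
  expect_error(energy_window(15, energy_resolution_fwhm_frac = 0), "0, 1")
})

test_that("projection without attenuation or PSF conserves activity", {
  ph <- desk_phantom()
  cfg <- acquisition_config(n_views = 12, seed = 1)
  sino <- forward_project(ph, cfg, with_attenuation = FALSE,
                          with_psf = FALSE)
  expected <- sum(ph$activity) * prod(ph$spec$voxel) / 1000 *
    cfg$sensitivity * cfg$time_per_frame * window_efficiency(cfg$window)
  per_view <- apply(sino, 3, sum)
  expect_true(all(abs(per_view / expected - 1) < 0.01))
  # zero activity in, zero counts out
  cold <- ph; cold$activity[] <- 0
  expect_true(all(forward_project(cold, cfg) == 0))
})

test_that("forward projection is linear in activity", {
  ph <- desk_phantom()
  cfg <- acquisition_config(n_views = 4, seed = 1)
  ph2 <- ph; ph2$activity <- 2.5 * ph$activity
  s1 <- forward_project(ph, cfg)
  s2 <- forward_project(ph2, cfg)
  expect_equal(s2, 2.5 * s1, tolerance = 1e-12)
})

test_that("a single ray through 10 cm of water attenuates by exp(-1.54)", {
  g <- c(21, 41, 5)
  vox <- 5                        # mm
  act <- array(0, g); mu <- array(0, g)
  act[11, 5, 3] <- 1              # point source below the slab
  mu[11, 11:30, 3] <- 0.154       # 20 voxels x 5 mm = 10 cm of water
  ph <- manual_phantom(act, mu, vox)
  cfg <- acquisition_config(n_views = 1, seed = 1)
  open <- forward_project(ph, cfg, with_attenuation = FALSE,
                          with_psf = FALSE)
  shad <- forward_project(ph, cfg, with_attenuation = TRUE,
                          with_psf = FALSE)
  expect_equal(sum(shad) / sum(open), exp(-1.54), tolerance = 1e-9)
})

test_that("scatter simulation hits the configured scatter fraction", {
  cfg <- acquisition_config(seed = 1)
  prim <- array(10, c(24, 24, 3))
  sc <- simulate_scatter(prim, cfg, bin_size = c(5.5, 5.5))
  for (v in 1:3) {
    s <- sum(sc$photopeak[, , v]); p <- sum(prim[, , v])
    expect_equal(s / (s + p), cfg$window$scatter_fraction, tolerance = 1e-9)
    expect_equal(s, p / 3, tolerance = 0.01)      # SF 0.25 -> s = p/3
  }
  expect_true(all(simulate_scatter(prim * 0, cfg)$photopeak == 0))
  tiny <- acquisition_config(window = energy_window(15,
                                                    scatter_fraction = 1e-12))
  expect_lt(sum(simulate_scatter(prim, tiny)$photopeak), 1e-6)
  expect_error(simulate_scatter(prim - 100, cfg), "nonnegative")
})

test_that("Poisson sampling is reproducible and has the right moments", {
  zero <- add_poisson(array(0, c(5, 5, 2)), seed = 7)
  expect_true(all(zero == 0))
  e <- array(50, c(100, 100, 1))
  a <- add_poisson(e, seed = 11)
  b <- add_poisson(e, seed = 11)
  expect_identical(a, b)
  se <- sqrt(50 / length(e))
  expect_lt(abs(mean(a) - 50), 3 * se)
  expect_error(add_poisson(e - 100, 1), "nonnegative")
})

test_that("time rebinning behaves like binomial thinning of one stream", {
  counts <- add_poisson(array(30, c(16, 16, 4)), seed = 3)
  ps <- manual_projection_set(counts, counts, time = 120)
  same <- rebin_time(ps, 120, seed = 5)
  expect_identical(same$photopeak, ps$photopeak)
  none <- rebin_time(ps, 0, seed = 5)
  expect_true(all(none$photopeak == 0))
  third <- rebin_time(ps, 40, seed = 5)
  N <- sum(ps$photopeak)
  sigma <- sqrt(N * (1 / 3) * (2 / 3))
  expect_lt(abs(sum(third$photopeak) - N / 3), 3 * sigma)
  expect_error(rebin_time(ps, 240), "exceeds")
})

test_that("two-step rebinning is distributionally equivalent to one step", {
  counts <- add_poisson(array(20, c(12, 12, 3)), seed = 9)
  ps <- manual_projection_set(counts, counts, time = 120)
  tot2 <- tot1 <- numeric(50)
  for (s in 1:50) {
    tot2[s] <- sum(rebin_time(rebin_time(ps, 60, seed = s), 30,
                              seed = 1000 + s)$photopeak)
    tot1[s] <- sum(rebin_time(ps, 30, seed = 2000 + s)$photopeak)
  }
  N <- sum(ps$photopeak)
  se <- sqrt(2 * N * 0.25 * 0.75 / 50)
  expect_lt(abs(mean(tot2) - mean(tot1)), 3 * se)
})
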