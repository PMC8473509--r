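# Metric formulas and the NEMA-style background ROI layout.

test_that("VOI statistics use the (n-1)-denominator SD", {
  vol <- array(2.5, c(8, 8, 4))
  mask <- array(FALSE, c(8, 8, 4)); mask[2:4, 2:4, 2] <- TRUE
  vs <- measure_voi(vol, mask, voxel = 2)
  expect_equal(vs$mean, 2.5)
  expect_equal(vs$sd, 0)
  expect_equal(vs$volume_ml, 9 * 8 / 1000)
  vol2 <- array(0, c(3, 1, 1)); vol2[, 1, 1] <- c(1, 2, 3)
  vs2 <- measure_voi(vol2, array(TRUE, c(3, 1, 1)), voxel = 1)
  expect_equal(vs2$mean, 2)
  expect_equal(vs2$sd, 1)
  expect_equal(measure_voi(vol * 0, mask, voxel = 2)$mean, 0)
  expect_error(measure_voi(vol, mask & FALSE, voxel = 2), "empty")
})

test_that("recovery coefficient is a percent ratio", {
  expect_equal(recovery_coefficient(0.20, 0.20), 100)
  expect_equal(recovery_coefficient(0.10, 0.20), 50)
  expect_equal(recovery_coefficient(0.21340, 0.20), 106.70)
  expect_error(recovery_coefficient(0.1, 0), "actual")
  expect_error(recovery_coefficient(-0.1, 0.2), "measured")
})

test_that("percent contrast normalizes by the true ratio", {
  expect_equal(percent_contrast(0.2, 0.00625, 0.2, 0.00625), 100)
  expect_equal(percent_contrast(1, 1, 4, 1), 0)
  expect_equal(percent_contrast(3, 1, 4, 1), 100 * (3 - 1) / (4 - 1))
  expect_error(percent_contrast(3, 1, 2, 2), "undefined")
  expect_error(percent_contrast(3, 0, 4, 1), "background")
})

test_that("background COV is SD over mean in percent", {
  expect_equal(background_cov(0, 10), 0)
  expect_equal(background_cov(10, 10), 100)
  expect_equal(background_cov(8.6, 10), 86)
  expect_error(background_cov(1, 0), "background")
})

test_that("default background ROI layout yields 60 ROIs per sphere size", {
  ph <- desk_phantom()
  rois <- place_background_rois(ph)
  counts <- table(rois$roi_mm)
  expect_equal(length(counts), 6)
  expect_true(all(counts == 60))            # 12 positions x 5 slices
  expect_true(all(lengths(rois$voxels) > 0))
  # ROI voxels never intersect sphere voxels
  sphere_idx <- which(ph$labels >= 2)
  expect_length(intersect(unlist(rois$voxels), sphere_idx), 0)
})

test_that("infeasible ROI layouts fail with a conflict listing", {
  ph <- desk_phantom()
  expect_error(place_background_rois(ph, edge_margin = 60), "infeasible")
  bad <- rbind(c(0, 57.2))                  # on the sphere ring
  expect_error(place_background_rois(ph, positions = bad), "overlaps sphere")
})

test_that("quantifying the ground-truth volume is perfect", {
  ph <- desk_phantom()
  rois <- place_background_rois(ph)
  q <- quantify(ph$activity, ph, rois)
  expect_equal(nrow(q), 6)
  expect_equal(q$rc, rep(100, 6))
  expect_equal(q$contrast, rep(100, 6), tolerance = 1e-10)
  expect_equal(q$cov, rep(0, 6))
  expect_equal(q$sd, rep(0, 6))
  # half the activity: RC halves, contrast is scale-invariant
  q2 <- quantify(ph$activity * 0.5, ph, rois)
  expect_equal(q2$rc, rep(50, 6))
  expect_equal(q2$contrast, rep(100, 6), tolerance = 1e-10)
  # spheres filled at background level: no contrast
  flat <- ph$activity
  flat[ph$labels >= 2] <- ph$spec$background_conc
  q3 <- quantify(flat, ph, rois)
  expect_equal(q3$contrast, rep(0, 6), tolerance = 1e-10)
})

test_that("contrast is invariant to global rescaling on arbitrary volumes", {
  ph <- desk_phantom()
  rois <- place_background_rois(ph)
  set.seed(12)
  vol <- ph$activity * array(runif(length(ph$activity), 0.5, 1.5),
                             dim(ph$activity))
  vol[ph$labels == 1] <- vol[ph$labels == 1] + 1e-4
  qa <- quantify(vol, ph, rois)
  qb <- quantify(vol * 7.3, ph, rois)
  expect_equal(qa$contrast, qb$contrast, tolerance = 1e-10)
  expect_equal(qb$rc, qa$rc * 7.3, tolerance = 1e-10)
})

test_that("heavy smoothing orders RC by sphere size", {
  ph <- desk_phantom()
  sm <- gaussian_postfilter(ph$activity, 12, voxel = ph$spec$voxel)
  q <- quantify(sm, ph)
  expect_gte(q$rc[q$sphere_mm == 37], q$rc[q$sphere_mm == 10])
  expect_lt(q$rc[q$sphere_mm == 10], 100)
})

test_that("quantification is deterministic given identical masks", {
  ph <- desk_phantom()
  rois <- place_background_rois(ph)
  sm <- gaussian_postfilter(ph$activity, 6, voxel = ph$spec$voxel)
  expect_identical(quantify(sm, ph, rois), quantify(sm, ph, rois))
})
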