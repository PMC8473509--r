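# Quantification metrics: per-sphere mean uptake and SD, recovery
# coefficient RC = 100 * measured / actual, NEMA NU 2 percent contrast
# Q = 100 * (C_H/C_B - 1) / (a_H/a_B - 1), and background variability
# COV = 100 * SD_B / C_B over size-matched background ROIs.

#' Mean and SD over a volume of interest
#'
#' @param volume A `recon_volume` or plain 3-D array.
#' @param mask Logical array of the same shape, at least one `TRUE` voxel.
#' @param voxel Voxel size (mm) for plain arrays.
#' @return One-row tibble: `mean`, `sd` ((n-1)-denominator), `n_voxels`,
#'   `volume_ml`.
#' @export
measure_voi <- function(volume, mask, voxel = NULL) {
  vals <- if (inherits(volume, "recon_volume")) volume$values else volume
  if (inherits(volume, "recon_volume")) voxel <- volume$voxel
  if (is.null(voxel)) abort("voxel required for plain arrays")
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  if (!all(dim(vals) == dim(mask))) abort("mask/volume grid mismatch")
  n <- sum(mask)
  if (n == 0) abort("empty VOI mask")
  v <- vals[mask]
  tibble(mean = mean(v), sd = if (n > 1) sd(v) else 0,
         n_voxels = as.integer(n), volume_ml = n * prod(voxel) / 1000)
}

#' Recovery coefficient
#'
#' `100 * measured / actual` percent; vectorized.
#'
#' @param measured Mean measured activity concentration (MBq/ml), >= 0.
#' @param actual True activity concentration (MBq/ml), > 0.
#' @return RC in percent.
#' @export
recovery_coefficient <- function(measured, actual) {
  if (any(actual <= 0)) abort("actual concentration must be > 0")
  if (any(measured < 0)) abort("measured concentration must be >= 0")
  100 * measured / actual
}

#' NEMA percent contrast of a hot sphere
#'
#' `100 * (C_H/C_B - 1) / (a_H/a_B - 1)`: measured sphere-to-background
#' contrast normalized by the true concentration ratio. Invariant to global
#' rescaling of the image.
#'
#' @param C_H,C_B Measured sphere and background means (counts or MBq/ml).
#' @param a_H,a_B True sphere and background concentrations (MBq/ml).
#' @return Percent contrast.
#' @export
percent_contrast <- function(C_H, C_B, a_H, a_B) {
  if (any(C_B <= 0)) abort("background mean must be > 0")
  if (any(a_H == a_B)) abort("contrast undefined when a_H = a_B")
  100 * (C_H / C_B - 1) / (a_H / a_B - 1)
}

#' Background variability (COV)
#'
#' `100 * SD_j / C_B`: standard deviation of the size-matched background ROI
#' means over their average, in percent.
#'
#' @param SD_j SD of the background ROI means.
#' @param C_B Average background ROI mean, > 0.
#' @return COV in percent.
#' @export
background_cov <- function(SD_j, C_B) {
  if (any(C_B <= 0)) abort("background mean must be > 0")
  if (any(SD_j < 0)) abort("SD must be >= 0")
  100 * SD_j / C_B
}

# Default in-plane background ROI centres (mm): 7 on an upper arc plus 5
# lower positions, all clear of the sphere ring and >= 15 mm inside the
# body edge for ROI diameters up to 37 mm.
default_roi_positions <- function() {
  upper_th <- seq(0, 180, by = 30) * pi / 180
  rbind(
    cbind(105 * cos(upper_th), 105 * sin(upper_th)),
    c(75, -35), c(-75, -35), c(0, -46),
    c(100, -20), c(-100, -20)
  )
}

#' Place NEMA-style background ROIs
#'
#' For each sphere diameter, circular 2-D ROIs of that diameter are placed
#' in the background compartment at 12 in-plane positions on the central
#' slice and on slices +/-1 cm and +/-2 cm (60 ROIs per size). Placement is
#' validated: every ROI must stay >= `edge_margin` from the body edge and
#' must not overlap any sphere; infeasible layouts raise an error listing
#' the conflicts.
#'
#' @param phantom A `spect_phantom`.
#' @param diameters ROI diameters in mm (default: the phantom's sphere
#'   diameters).
#' @param positions 2-column matrix of in-plane ROI centres (mm).
#' @param slice_offsets_mm Axial offsets of the ROI slices relative to the
#'   sphere plane.
#' @param edge_margin Minimum in-plane distance (mm) from ROI boundary to
#'   body edge.
#' @return Tibble with one row per ROI: `roi_mm`, `roi_id`, `x`, `y`,
#'   `z_mm`, and `voxels` (list-column of voxel indices into the grid).
#' @export
place_background_rois <- function(phantom,
                                  diameters = NULL,
                                  positions = default_roi_positions(),
                                  slice_offsets_mm = c(-20, -10, 0, 10, 20),
                                  edge_margin = 15) {
  stopifnot(inherits(phantom, "spect_phantom"))
  spec <- phantom$spec
  sp <- spec$spheres
  if (is.null(diameters)) diameters <- sp$diameter_mm
  ax <- grid_axes(spec$grid, spec$voxel)

  conflicts <- character()
  for (dmm in diameters) {
    r_roi <- dmm / 2
    ed <- body_edge_distance(positions[, 1], positions[, 2], spec$body)
    bad_edge <- which(ed < r_roi + edge_margin)
    for (b in bad_edge) {
      conflicts <- c(conflicts, sprintf(
        "ROI %.0f mm at (%.0f, %.0f): only %.1f mm to body edge",
        dmm, positions[b, 1], positions[b, 2], ed[b]))
    }
    if (nrow(sp) > 0) {
      dd <- sqrt(outer(positions[, 1], sp$x, "-")^2 +
                 outer(positions[, 2], sp$y, "-")^2)
      lim <- matrix(r_roi + sp$diameter_mm / 2, nrow(positions),
                    nrow(sp), byrow = TRUE)
      bad <- which(dd < lim, arr.ind = TRUE)
      for (i in seq_len(nrow(bad))) {
        conflicts <- c(conflicts, sprintf(
          "ROI %.0f mm at (%.0f, %.0f) overlaps sphere %.0f mm",
          dmm, positions[bad[i, 1], 1], positions[bad[i, 1], 2],
          sp$diameter_mm[bad[i, 2]]))
      }
    }
    zlim <- spec$body$length / 2 - edge_margin
    for (z in slice_offsets_mm) {
      if (abs(z) > zlim) {
        conflicts <- c(conflicts, sprintf(
          "ROI slice at %+.0f mm is within %.0f mm of the body end", z,
          edge_margin))
      }
    }
  }
  if (length(conflicts) > 0) {
    abort(c("infeasible background-ROI layout:", unique(conflicts)))
  }

  nx <- spec$grid[1]; nyg <- spec$grid[2]
  rows <- list()
  for (dmm in diameters) {
    r_roi <- dmm / 2
    rid <- 0L
    for (z in slice_offsets_mm) {
      k <- which.min(abs(ax[[3]] - z))
      for (p in seq_len(nrow(positions))) {
        rid <- rid + 1L
        inroi <- outer((ax[[1]] - positions[p, 1])^2,
                       (ax[[2]] - positions[p, 2])^2, "+") <= r_roi^2
        idx <- which(inroi)
        vox <- (k - 1L) * nx * nyg + idx
        rows[[length(rows) + 1L]] <- tibble(
          roi_mm = dmm, roi_id = rid,
          x = positions[p, 1], y = positions[p, 2], z_mm = ax[[3]][k],
          voxels = list(vox))
      }
    }
  }
  bind_rows(rows)
}

#' Quantify a reconstructed volume against its phantom
#'
#' Computes, per hot sphere: VOI mean and SD (ground-truth label masks),
#' size-matched background statistics from the NEMA-style ROI layout,
#' recovery coefficient, percent contrast and background COV.
#'
#' @param volume A `recon_volume` (or plain array on the phantom grid).
#' @param phantom The `spect_phantom` the data came from.
#' @param rois Optional precomputed ROI table from
#'   [place_background_rois()] (reused across repeated calls).
#' @return A `quant_result` tibble, one row per sphere: `sphere_mm`,
#'   `label`, `mean`, `sd`, `n_voxels`, `volume_ml`, `bg_mean`, `bg_sd`,
#'   `n_rois`, `rc`, `contrast`, `cov`, `a_H`, `a_B`, `tb_ratio`.
#' @export
quantify <- function(volume, phantom, rois = NULL) {
  stopifnot(inherits(phantom, "spect_phantom"))
  vals <- if (inherits(volume, "recon_volume")) volume$values else volume
  if (!all(dim(vals) == phantom$spec$grid)) abort("grid mismatch")
  spec <- phantom$spec
  sp <- spec$spheres
  if (is.null(rois)) rois <- place_background_rois(phantom)

  bg <- rois %>%
    mutate(roi_mean = map_dbl(.data$voxels, function(i) mean(vals[i]))) %>%
    group_by(.data$roi_mm) %>%
    summarise(bg_mean = mean(.data$roi_mean),
              bg_sd = sd(.data$roi_mean),
              n_rois = dplyr::n(), .groups = "drop")

  masks <- voi_masks(phantom)
  res <- lapply(seq_len(nrow(sp)), function(i) {
    vs <- measure_voi(vals, masks[[as.character(sp$label[i])]],
                      voxel = spec$voxel)
    mutate(vs, sphere_mm = sp$diameter_mm[i], label = sp$label[i])
  }) %>% bind_rows()

  out <- res %>%
    left_join(bg, by = c(sphere_mm = "roi_mm")) %>%
    mutate(
      rc = recovery_coefficient(.data$mean, spec$sphere_conc),
      contrast = percent_contrast(.data$mean, .data$bg_mean,
                                  spec$sphere_conc, spec$background_conc),
      cov = background_cov(.data$bg_sd, .data$bg_mean),
      a_H = spec$sphere_conc, a_B = spec$background_conc,
      tb_ratio = spec$tb_ratio) %>%
    select(all_of(c("sphere_mm", "label", "mean", "sd", "n_voxels",
                    "volume_ml", "bg_mean", "bg_sd", "n_rois", "rc",
                    "contrast", "cov", "a_H", "a_B", "tb_ratio"))) %>%
    arrange(dplyr::desc(.data$sphere_mm))
  if (inherits(volume, "recon_volume")) {
    attr(out, "recon_config") <- volume$config
  }
  class(out) <- c("quant_result", class(out))
  out
}
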