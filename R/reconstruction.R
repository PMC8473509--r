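# OSEM reconstruction with switchable corrections: attenuation (AC) puts the
# mu-map in the system matrix, resolution recovery (RR) puts the
# depth-dependent PSF in it, scatter correction (SC) adds a dual-energy-window
# estimate inside the forward model (Ax + s), preserving Poisson statistics
# and nonnegativity.

#' Convert Gaussian FWHM to standard deviation
#'
#' @param fwhm Full width at half maximum (mm), >= 0.
#' @return `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (any(fwhm < 0)) abort("fwhm must be nonnegative")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Reconstruction settings
#'
#' @param iterations OSEM iterations (study sweep: 1-90).
#' @param subsets Ordered subsets (study sweep: 2-30; 1 gives plain MLEM).
#' @param corrections Character subset of `c("AC", "SC", "RR")`.
#' @param post_filter_fwhm Gaussian post-filter FWHM in mm (study sweep:
#'   0.7-6.99), or `NULL` for no filter.
#' @param dew_k Dual-energy-window scaling factor k (classic value 0.5).
#' @param initial_value Positive uniform starting value inside the support.
#' @param scatter_mode `"additive"` (scatter inside the forward model,
#'   default) or `"presubtract"` (subtract the estimate from the data and
#'   clip at zero, as in older dual-energy-window practice).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(iterations = 35L,
                         subsets = 20L,
                         corrections = c("AC", "SC", "RR"),
                         post_filter_fwhm = NULL,
                         dew_k = 0.5,
                         initial_value = 1,
                         scatter_mode = c("additive", "presubtract")) {
  scatter_mode <- match.arg(scatter_mode)
  stopifnot(iterations >= 1, subsets >= 1, initial_value > 0, dew_k >= 0)
  if (!all(corrections %in% c("AC", "SC", "RR"))) {
    abort("corrections must be a subset of {AC, SC, RR}")
  }
  if (!is.null(post_filter_fwhm) && post_filter_fwhm <= 0) {
    abort("post_filter_fwhm must be > 0 when set")
  }
  structure(list(
    iterations = as.integer(iterations),
    subsets = as.integer(subsets),
    corrections = unique(corrections),
    post_filter_fwhm = post_filter_fwhm,
    dew_k = dew_k,
    initial_value = initial_value,
    scatter_mode = scatter_mode
  ), class = "recon_config")
}

#' Dual-energy-window scatter estimate
#'
#' Photopeak-window scatter approximated from the lower-window counts:
#' `k * (W_pp / W_sc) * C_sc` per bin, where the W are the window widths in
#' keV.
#'
#' @param scatterwin_counts Lower-window count array (any shape).
#' @param k Dimensionless scaling factor (classic value 0.5).
#' @param photopeak_width,scatterwin_width Window widths in keV.
#' @return Object of class `scatter_estimate` with `values` (same shape as
#'   the input), `k`, `width_ratio` and `method = "DEW"`.
#' @export
dew_scatter_estimate <- function(scatterwin_counts, k = 0.5,
                                 photopeak_width = 21,
                                 scatterwin_width = 12) {
  if (photopeak_width <= 0 || scatterwin_width <= 0) {
    abort("window widths must be > 0")
  }
  if (any(scatterwin_counts < 0)) abort("counts must be nonnegative")
  ratio <- photopeak_width / scatterwin_width
  structure(list(values = k * ratio * scatterwin_counts,
                 k = k, width_ratio = ratio, method = "DEW"),
            class = "scatter_estimate")
}

# Stride partition of views into nearly-equal, angularly spread subsets.
subset_views <- function(n_views, n_subsets) {
  if (n_subsets > n_views) abort("more subsets than views")
  lapply(seq_len(n_subsets), function(k) seq(k, n_views, by = n_subsets))
}

# Poisson log-likelihood of counts y under expectation f (monotone under
# MLEM; used by the invariant tests).
poisson_loglik <- function(y, f) {
  if (any(f < 0)) abort("expectations must be nonnegative")
  ok <- f > 0
  if (any(y[!ok] > 0)) return(-Inf)
  sum(y[ok] * log(f[ok]) - f[ok])
}

# Abstract OSEM/MLEM engine over an operator interface. `subsets` is a list
# of view-id vectors; fp(x, views) returns the flattened expected data for
# those views, bp(r, views) its exact adjoint; y_list / s_list are the data
# and additive scatter per subset. Voxels whose subset sensitivity falls
# below sens_floor * max are frozen. Returns the final image and any
# recorded full-iteration images.
osem_core <- function(x0, n_iter, subsets, fp, bp, y_list, s_list = NULL,
                      record = NULL, sens_floor = 1e-8) {
  x <- x0
  ns <- length(subsets)
  sens <- vector("list", ns)
  live <- vector("list", ns)
  for (k in seq_len(ns)) {
    sens[[k]] <- bp(rep(1, length(y_list[[k]])), subsets[[k]])
    live[[k]] <- sens[[k]] > sens_floor * max(sens[[k]])
  }
  iterates <- list()
  for (it in seq_len(n_iter)) {
    for (k in seq_len(ns)) {
      f <- fp(x, subsets[[k]])
      if (!is.null(s_list)) f <- f + s_list[[k]]
      ratio <- ifelse(f > 0, y_list[[k]] / f, 0)
      u <- bp(ratio, subsets[[k]])
      upd <- ifelse(live[[k]], u / pmax(sens[[k]], .Machine$double.xmin), 1)
      x <- x * upd
    }
    if (!is.null(record) && it %in% record) {
      iterates[[as.character(it)]] <- x
    }
  }
  list(x = x, iterates = iterates)
}

#' OSEM reconstruction of a projection set
#'
#' Multiplicative ordered-subsets EM: per subset,
#' `x <- x / (A' 1) * A' (y / (A x + s))`, where the system matrix A
#' contains the attenuation factors when `"AC"` is among the corrections and
#' the depth-dependent PSF when `"RR"` is, and s is the dual-energy-window
#' scatter estimate when `"SC"` is (zero otherwise). The calibration
#' (sensitivity x frame time x window efficiency x voxel volume) is part of
#' A, so the image is in MBq/ml directly. Views are assigned to subsets by
#' stride for maximal angular spread. An optional Gaussian post-filter is
#' applied last.
#'
#' @param projections A `projection_set`.
#' @param mu_map Attenuation map (cm^-1) on the phantom grid; required for
#'   `"AC"`.
#' @param config A [recon_config()].
#' @param record_iterations Optional integer vector: additionally return the
#'   image after these full iterations (post-filtered the same way).
#' @return Object of class `recon_volume`: `values` (MBq/ml array),
#'   `voxel`, `config`, acquisition provenance, and (when requested)
#'   `iterates`, a named list of value arrays.
#' @export
osem_reconstruct <- function(projections, mu_map = NULL, config = recon_config(),
                             record_iterations = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(config, "recon_config"))
  ac <- "AC" %in% config$corrections
  rr <- "RR" %in% config$corrections
  sc <- "SC" %in% config$corrections
  if (ac && is.null(mu_map)) abort("AC requested but no mu_map given")
  spec <- projections$phantom_spec
  g <- spec$grid
  voxel <- spec$voxel
  if (ac && !all(dim(mu_map) == g)) abort("mu_map grid mismatch")
  acq <- projections$config
  d <- dim(projections$photopeak)
  if (d[1] != g[1] || d[2] != g[3]) abort("projection/grid shape mismatch")

  proj <- make_projector(g, voxel, acq$view_angles,
                         psf = if (rr) acq$psf_model else NULL,
                         mu = if (ac) mu_map else NULL)
  scale <- count_scale(acq, voxel)
  nbin <- d[1] * d[2]

  fp <- function(x, views) {
    out <- numeric(nbin * length(views))
    for (i in seq_along(views)) {
      out[((i - 1) * nbin + 1):(i * nbin)] <- proj$fp_view(x, views[i])
    }
    out * scale
  }
  bp <- function(r, views) {
    acc <- array(0, g)
    for (i in seq_along(views)) {
      rv <- matrix(r[((i - 1) * nbin + 1):(i * nbin)], d[1], d[2])
      acc <- acc + proj$bp_view(rv, views[i])
    }
    acc * scale
  }

  subs <- subset_views(acq$n_views, config$subsets)
  y_list <- lapply(subs, function(v) as.vector(projections$photopeak[, , v]))
  s_list <- NULL
  if (sc) {
    est <- dew_scatter_estimate(
      projections$scatterwin, k = config$dew_k,
      photopeak_width = acq$window$photopeak_width_kev,
      scatterwin_width = acq$window$scatter_width_kev)
    if (config$scatter_mode == "additive") {
      s_list <- lapply(subs, function(v) as.vector(est$values[, , v]))
    } else {
      y_list <- lapply(seq_along(subs), function(k) {
        pmax(y_list[[k]] - as.vector(est$values[, , subs[[k]]]), 0)
      })
    }
  }

  support <- if (ac) (mu_map > 0) else array(TRUE, g)
  x0 <- array(0, g)
  x0[support] <- config$initial_value

  fit <- osem_core(x0, config$iterations, subs, fp, bp, y_list, s_list,
                   record = record_iterations)

  finish <- function(x) {
    if (!is.null(config$post_filter_fwhm)) {
      x <- gaussian_filter_array(x, voxel, config$post_filter_fwhm)
    }
    x
  }
  out <- structure(list(
    values = finish(fit$x),
    voxel = voxel,
    config = config,
    acquisition = acq,
    phantom_spec = spec
  ), class = "recon_volume")
  if (!is.null(record_iterations)) {
    out$iterates <- lapply(fit$iterates, finish)
  }
  out
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf(
    "<recon_volume> %s at %s mm; OSEM %d it x %d subsets [%s]%s\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$voxel, 3), collapse = "x"),
    x$config$iterations, x$config$subsets,
    paste(x$config$corrections, collapse = "+"),
    if (is.null(x$config$post_filter_fwhm)) "" else
      sprintf(", filter %.2f mm", x$config$post_filter_fwhm)))
  invisible(x)
}

# Separable 3-D Gaussian convolution of an array, FWHM in mm.
gaussian_filter_array <- function(x, voxel, fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  d <- dim(x)
  G1 <- gauss_toeplitz(d[1], sigma / voxel[1])
  G2 <- gauss_toeplitz(d[2], sigma / voxel[2])
  G3 <- gauss_toeplitz(d[3], sigma / voxel[3])
  m <- G1 %*% matrix(x, d[1], d[2] * d[3])
  x <- array(as.matrix(m), d)
  for (k in seq_len(d[3])) x[, , k] <- x[, , k] %*% G2
  m <- matrix(x, d[1] * d[2], d[3]) %*% G3
  array(as.matrix(m), d)
}

#' Gaussian post-filter
#'
#' Isotropic 3-D Gaussian smoothing of a reconstructed volume, parameterized
#' by FWHM in mm. Total activity is preserved (unit-sum kernel) up to
#' truncation at the grid boundary.
#'
#' @param volume A `recon_volume` (or plain 3-D array with `voxel` given).
#' @param fwhm Filter FWHM in mm, > 0.
#' @param voxel Voxel size (mm), only for plain arrays.
#' @return Same type as the input.
#' @export
gaussian_postfilter <- function(volume, fwhm, voxel = NULL) {
  if (fwhm <= 0) abort("fwhm must be > 0")
  if (inherits(volume, "recon_volume")) {
    volume$values <- gaussian_filter_array(volume$values, volume$voxel, fwhm)
    volume$config$post_filter_fwhm <- fwhm
    volume
  } else {
    if (is.null(voxel)) abort("voxel required for plain arrays")
    if (length(voxel) == 1) voxel <- rep(voxel, 3)
    gaussian_filter_array(volume, voxel, fwhm)
  }
}
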