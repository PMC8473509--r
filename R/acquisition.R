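# Synthetic acquisition: energy-window model, step-and-shoot geometry,
# noiseless forward projection, stationary-kernel scatter, Poisson noise and
# list-mode-style time rebinning.

#' Energy-window model for a CZT photopeak acquisition
#'
#' Describes the photopeak window (140 keV +/- 7.5% or +/- 10%), the lower
#' scatter window (120 keV +/- 5%) used for dual-energy-window scatter
#' estimation, the detector energy resolution, and the scatter fraction of
#' accepted photopeak events. The default scatter fraction grows with window
#' width (0.25 at 15%, 0.32 at 20%): a wider window accepts more
#' down-scattered photons.
#'
#' @param width_pct Full photopeak window width as percent of 140 keV
#'   (15 or 20 in the study design).
#' @param photopeak_center,scatter_center Window centres in keV.
#' @param scatter_halfwidth_frac Scatter-window half-width fraction (0.05).
#' @param energy_resolution_fwhm_frac Detector energy resolution as FWHM
#'   fraction at 140 keV; default 0.06 (CZT-like).
#' @param scatter_fraction Fraction of accepted photopeak-window events that
#'   are scatter; `NULL` uses the width-dependent default.
#' @param scatterwin_to_scatter Ratio of scatter-window counts to
#'   photopeak-window scatter counts (calibration of the simulated lower
#'   window).
#' @return An object of class `energy_window`.
#' @export
energy_window <- function(width_pct = 15,
                          photopeak_center = 140,
                          scatter_center = 120,
                          scatter_halfwidth_frac = 0.05,
                          energy_resolution_fwhm_frac = 0.06,
                          scatter_fraction = NULL,
                          scatterwin_to_scatter = 1.0) {
  hw <- width_pct / 200
  if (is.null(scatter_fraction)) {
    scatter_fraction <- 0.25 + (width_pct - 15) * (0.32 - 0.25) / 5
  }
  fr <- c(hw, scatter_halfwidth_frac, energy_resolution_fwhm_frac,
          scatter_fraction)
  if (any(fr <= 0) || any(fr >= 1)) {
    abort("window fractions must lie in (0, 1)")
  }
  structure(list(
    width_pct = width_pct,
    photopeak_center = photopeak_center,
    photopeak_halfwidth_frac = hw,
    scatter_center = scatter_center,
    scatter_halfwidth_frac = scatter_halfwidth_frac,
    energy_resolution_fwhm_frac = energy_resolution_fwhm_frac,
    scatter_fraction = scatter_fraction,
    scatterwin_to_scatter = scatterwin_to_scatter,
    photopeak_width_kev = 2 * hw * photopeak_center,
    scatter_width_kev = 2 * scatter_halfwidth_frac * scatter_center
  ), class = "energy_window")
}

#' Fraction of the photopeak accepted by an energy window
#'
#' Models the emitted photopeak as a Gaussian centred at 140 keV with FWHM
#' equal to the detector energy resolution, and integrates it over the
#' window bounds.
#'
#' @param window An [energy_window()].
#' @param which `"photopeak"` or `"scatter"` (the lower window; primary
#'   photons barely reach it at CZT resolution).
#' @return Acceptance fraction in \[0, 1\].
#' @export
window_efficiency <- function(window, which = c("photopeak", "scatter")) {
  which <- match.arg(which)
  peak <- window$photopeak_center
  sigma <- fwhm_to_sigma(window$energy_resolution_fwhm_frac * peak)
  bounds <- if (which == "photopeak") {
    peak * (1 + c(-1, 1) * window$photopeak_halfwidth_frac)
  } else {
    window$scatter_center * (1 + c(-1, 1) * window$scatter_halfwidth_frac)
  }
  pnorm(bounds[2], peak, sigma) - pnorm(bounds[1], peak, sigma)
}

#' Acquisition protocol configuration
#'
#' Step-and-shoot SPECT protocol: `n_views` frames over a full `arc`
#' (default 60 frames at 6 degrees), 128-bin-class detector rows at the
#' phantom voxel pitch, `time_per_frame` seconds per view. `sensitivity` is
#' the per-view system calibration factor (counts per second per MBq in the
#' field of view); its default puts roughly 1e6 photopeak counts in a 120 s,
#' 32:1 view set.
#'
#' @param n_views Number of views (default 60).
#' @param arc Total rotation in degrees (360).
#' @param time_per_frame Seconds per frame, in \[1, 120\].
#' @param sensitivity Counts s^-1 MBq^-1 per view.
#' @param psf_fwhm_intercept,psf_fwhm_slope Depth-dependent collimator
#'   resolution model FWHM(d) = intercept + slope * d, in mm and mm/mm.
#' @param scatter_kernel_sigma Stationary scatter kernel sigma in mm.
#' @param window An [energy_window()].
#' @param seed Integer seed for all acquisition randomness.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_views = 60L,
                               arc = 360,
                               time_per_frame = 120,
                               sensitivity = 5.0,
                               psf_fwhm_intercept = 4.0,
                               psf_fwhm_slope = 0.045,
                               scatter_kernel_sigma = 30,
                               window = energy_window(15),
                               seed = 1L) {
  stopifnot(n_views >= 1, arc > 0, sensitivity > 0)
  if (time_per_frame < 1 || time_per_frame > 120) {
    abort("time_per_frame must lie in [1, 120] seconds")
  }
  structure(list(
    n_views = as.integer(n_views),
    arc = arc,
    view_step = arc / n_views,
    view_angles = seq(0, arc - arc / n_views, length.out = n_views),
    time_per_frame = time_per_frame,
    sensitivity = sensitivity,
    psf_model = list(intercept = psf_fwhm_intercept, slope = psf_fwhm_slope),
    scatter_kernel_sigma = scatter_kernel_sigma,
    window = window,
    seed = as.integer(seed)
  ), class = "acquisition_config")
}

# Counts-per-(MBq/ml voxel) calibration factor of the forward model.
count_scale <- function(config, voxel) {
  config$sensitivity * config$time_per_frame *
    window_efficiency(config$window, "photopeak") * prod(voxel) / 1000
}

#' Noiseless primary-photon forward projection
#'
#' Expected photopeak-window counts of unscattered photons for every view:
#' rotate the activity grid to the view angle, attenuate along the ray axis
#' (`with_attenuation`), blur with the depth-dependent collimator PSF
#' (`with_psf`), sum to the detector, and scale by sensitivity x frame time
#' x window efficiency x voxel volume.
#'
#' @param phantom A `spect_phantom`.
#' @param config An [acquisition_config()].
#' @param with_attenuation,with_psf Physics switches (both on for realistic
#'   data; off for conservation tests).
#' @return Array of expected counts, dim = (transaxial bin, axial bin, view).
#' @export
forward_project <- function(phantom, config,
                            with_attenuation = TRUE, with_psf = TRUE) {
  stopifnot(inherits(phantom, "spect_phantom"),
            inherits(config, "acquisition_config"))
  g <- phantom$spec$grid
  proj <- make_projector(
    g, phantom$spec$voxel, config$view_angles,
    psf = if (with_psf) config$psf_model else NULL,
    mu = if (with_attenuation) phantom$mu else NULL)
  sino <- array(0, c(g[1], g[3], config$n_views))
  for (v in seq_len(config$n_views)) {
    sino[, , v] <- proj$fp_view(phantom$activity, v)
  }
  sino * count_scale(config, phantom$spec$voxel)
}

#' Stationary-kernel scatter simulation
#'
#' Adds the physical scatter the corrections must remove: each view of the
#' primary sinogram is convolved with a broad 2-D Gaussian (sigma
#' `scatter_kernel_sigma`) and scaled per view so scatter / (scatter +
#' primary) equals the window's scatter fraction. The lower-window signal is
#' a scaled copy of the photopeak scatter. This kernel model is deliberately
#' different from the dual-energy-window correction model, so scatter
#' correction is tested against model mismatch rather than its own inverse.
#'
#' @param primary Noiseless primary sinogram (bins x bins x views).
#' @param config An [acquisition_config()].
#' @param bin_size Detector bin size in mm (transaxial, axial); the kernel
#'   sigma is converted to bins with it.
#' @return List with `photopeak` (expected scatter counts inside the
#'   photopeak window) and `scatterwin` (expected lower-window counts).
#' @export
simulate_scatter <- function(primary, config, bin_size = c(4.4, 4.4)) {
  if (any(primary < 0)) abort("primary sinogram must be nonnegative")
  d <- dim(primary)
  bin_size <- rep(bin_size, length.out = 2)
  sf <- config$window$scatter_fraction
  Gx <- gauss_toeplitz(d[1], config$scatter_kernel_sigma / bin_size[1])
  Gz <- gauss_toeplitz(d[2], config$scatter_kernel_sigma / bin_size[2])
  sc <- array(0, d)
  for (v in seq_len(d[3])) {
    p <- matrix(primary[, , v], d[1], d[2])
    tot <- sum(p)
    if (tot <= 0) next
    s <- as.matrix(Gx %*% p %*% Gz)
    s_tot <- sum(s)
    if (s_tot > 0) sc[, , v] <- s * (sf / (1 - sf) * tot / s_tot)
  }
  list(photopeak = sc,
       scatterwin = sc * config$window$scatterwin_to_scatter)
}

#' Poisson count realization
#'
#' Independent Poisson draw per sinogram bin, reproducible from `seed` and
#' leaving the caller's RNG state untouched.
#'
#' @param expected Nonnegative expected-count array.
#' @param seed Integer seed.
#' @return Integer count array of the same shape.
#' @export
add_poisson <- function(expected, seed) {
  if (any(expected < 0)) abort("expected counts must be nonnegative")
  out <- with_rng(seed, rpois(length(expected), as.vector(expected)))
  array(out, dim(expected))
}

#' Simulate a full projection set
#'
#' Runs the acquisition chain: primary forward projection (attenuation +
#' PSF), scatter simulation, and (optionally) Poisson noise in both energy
#' windows. Windows are simulated as independent Poisson realizations of
#' their shared expectations.
#'
#' @param phantom A `spect_phantom`.
#' @param config An [acquisition_config()].
#' @param noise Draw Poisson counts? `FALSE` returns expected values
#'   (noiseless mode for convergence studies).
#' @return An object of class `projection_set`: `photopeak`, `scatterwin`
#'   count arrays (bins x bins x views), `truth` (noiseless primary),
#'   `view_angles`, `config`, and the originating `phantom_spec`.
#' @export
simulate_projections <- function(phantom, config, noise = TRUE) {
  primary <- forward_project(phantom, config)
  sc <- simulate_scatter(primary, config,
                         bin_size = phantom$spec$voxel[c(1, 3)])
  exp_pp <- primary + sc$photopeak
  if (noise) {
    pp <- add_poisson(exp_pp, child_seed(config$seed, "photopeak"))
    sw <- add_poisson(sc$scatterwin, child_seed(config$seed, "scatterwin"))
  } else {
    pp <- exp_pp
    sw <- sc$scatterwin
  }
  structure(list(
    photopeak = pp,
    scatterwin = sw,
    truth = primary,
    view_angles = config$view_angles,
    config = config,
    phantom_spec = phantom$spec,
    noise = noise
  ), class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf(
    "<projection_set> %d views, %dx%d bins, %g s/frame, %g%% window\n",
    length(x$view_angles), dim(x$photopeak)[1], dim(x$photopeak)[2],
    x$config$time_per_frame, x$config$window$width_pct))
  cat(sprintf("  photopeak counts %.3g, scatter-window counts %.3g\n",
              sum(x$photopeak), sum(x$scatterwin)))
  invisible(x)
}

#' List-mode-style time rebinning
#'
#' Emulates re-histogramming a stored event stream to a shorter frame time:
#' every bin is binomially thinned with retention `target_time /
#' time_per_frame`, i.e. a sub-sample of the same events, not an independent
#' acquisition.
#'
#' @param ps A `projection_set`.
#' @param target_time Target seconds per frame (<= acquired frame time).
#' @param seed Integer seed for the thinning.
#' @return A `projection_set` at the new frame time.
#' @export
rebin_time <- function(ps, target_time, seed = ps$config$seed + 1L) {
  stopifnot(inherits(ps, "projection_set"))
  full <- ps$config$time_per_frame
  if (target_time > full) abort("target_time exceeds acquired frame time")
  if (target_time < 0) abort("target_time must be nonnegative")
  p <- target_time / full
  thin <- function(counts, tag) {
    cnt <- round(counts)
    out <- with_rng(child_seed(seed, tag),
                    rbinom(length(cnt), size = as.vector(cnt), prob = p))
    array(out, dim(counts))
  }
  ps$photopeak <- thin(ps$photopeak, "photopeak")
  ps$scatterwin <- thin(ps$scatterwin, "scatterwin")
  ps$truth <- ps$truth * p
  ps$config$time_per_frame <- target_time
  ps
}
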