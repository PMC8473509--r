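# Digital NEMA IEC body phantom: D-shaped torso cross-section with six
# fillable hot spheres on a 114.4 mm circle, voxelized onto a regular grid
# as co-registered activity (MBq/ml), attenuation (cm^-1) and label volumes.

TC99M_HALF_LIFE_H <- 6.0058

#' Default hot-sphere set of the IEC body phantom
#'
#' Six spheres (inner diameters 37, 28, 22, 17, 13 and 10 mm) centred on a
#' 114.4 mm diameter circle in the central transaxial plane. The two smallest
#' spheres are placed at the bottom angles so the default background-ROI
#' layout keeps its 15 mm clearances.
#'
#' @param ring_radius Radius (mm) of the circle carrying the sphere centres.
#' @param diameters Sphere inner diameters in mm, largest first.
#' @param angles_deg Angular positions (degrees) matching `diameters`.
#' @return A tibble with columns `label`, `diameter_mm`, `x`, `y`, `z` (mm).
#' @export
default_spheres <- function(ring_radius = 57.2,
                            diameters = c(37, 28, 22, 17, 13, 10),
                            angles_deg = c(60, 120, 0, 180, 300, 240)) {
  stopifnot(length(diameters) == length(angles_deg), all(diameters > 0))
  th <- angles_deg * pi / 180
  tibble(
    label = seq_along(diameters) + 1L,
    diameter_mm = as.numeric(diameters),
    x = ring_radius * cos(th),
    y = ring_radius * sin(th),
    z = 0
  )
}

#' Specify an IEC body phantom realization
#'
#' Defines the activity, geometry and attenuation of a digital NEMA IEC body
#' phantom: a D-shaped body compartment filled with background activity
#' `sphere_conc / tb_ratio` and hot spheres filled at `sphere_conc`.
#'
#' @param tb_ratio Target-to-background activity concentration ratio
#'   (study values: 32, 16, 8, 4).
#' @param sphere_conc Hot-sphere activity concentration in MBq/ml at
#'   acquisition time (study values: 0.20, 0.11, 0.06, 0.03).
#' @param spheres Sphere table as from [default_spheres()]; may have zero rows.
#' @param voxel Voxel size in mm; scalar (isotropic) or length-3 vector.
#' @param grid Grid shape, 3 positive integers (x, y, z).
#' @param body Body-outline parameters in mm: `top_radius` of the upper
#'   half-disc, `half_width`, `depth` of the lower rectangular section,
#'   `corner_radius` of the rounded lower corners, and axial `length`.
#' @param mu_fill Linear attenuation coefficient of the fill (cm^-1);
#'   default 0.154, water at 140 keV.
#' @param lung_insert Model the central low-density cylindrical insert?
#'   Off by default (not used by the quantification metrics).
#' @param lung_radius,mu_lung Radius (mm) and attenuation (cm^-1) of the
#'   insert when enabled.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tb_ratio = 32,
                         sphere_conc = 0.20,
                         spheres = default_spheres(),
                         voxel = 3.3,
                         grid = c(128L, 128L, 64L),
                         body = list(top_radius = 150, half_width = 150,
                                     depth = 80, corner_radius = 77,
                                     length = 180),
                         mu_fill = 0.154,
                         lung_insert = FALSE,
                         lung_radius = 25,
                         mu_lung = 0.04) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  stopifnot(length(voxel) == 3, all(voxel > 0),
            length(grid) == 3, all(grid >= 1),
            tb_ratio > 0, sphere_conc >= 0, mu_fill >= 0)
  if (anyDuplicated(spheres$label)) abort("sphere labels must be unique")
  if (nrow(spheres) > 0 && any(spheres$label < 2)) {
    abort("sphere labels must be >= 2 (0 = outside, 1 = background)")
  }
  a_b <- sphere_conc / tb_ratio
  structure(list(
    tb_ratio = tb_ratio,
    sphere_conc = sphere_conc,
    background_conc = a_b,
    spheres = spheres,
    voxel = as.numeric(voxel),
    grid = as.integer(grid),
    body = body,
    mu_fill = mu_fill,
    lung_insert = lung_insert,
    lung_radius = lung_radius,
    mu_lung = mu_lung
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> T/B %g:1, spheres %.3g MBq/ml, background %.4g MBq/ml\n",
    x$tb_ratio, x$sphere_conc, x$background_conc))
  cat(sprintf("  grid %s at %s mm; %d spheres\n",
              paste(x$grid, collapse = "x"),
              paste(signif(x$voxel, 3), collapse = "x"), nrow(x$spheres)))
  invisible(x)
}

# Voxel-centre coordinates (mm) of a grid centred on the origin.
grid_axes <- function(grid, voxel) {
  lapply(1:3, function(a) (seq_len(grid[a]) - (grid[a] + 1) / 2) * voxel[a])
}

# 2-D D-shaped body outline membership test (vectorized over x, y in mm).
# Upper half: disc of top_radius; lower half: rectangle with rounded corners.
inside_body_2d <- function(x, y, body) {
  r <- body$top_radius; hw <- body$half_width
  d <- body$depth; rc <- body$corner_radius
  upper <- y >= 0 & x^2 + y^2 <= r^2
  lower <- y < 0 & y >= -d & abs(x) <= hw
  in_corner_zone <- y < -(d - rc) & abs(x) > hw - rc
  corner_ok <- (abs(x) - (hw - rc))^2 + (y + (d - rc))^2 <= rc^2
  lower & (!in_corner_zone | corner_ok) | upper
}

# Distance (mm) from an interior point to the nearest body boundary,
# used for ROI edge-margin checks. Conservative for the corner arcs.
body_edge_distance <- function(x, y, body) {
  r <- body$top_radius; hw <- body$half_width
  d <- body$depth; rc <- body$corner_radius
  cand <- cbind(
    ifelse(y >= 0, r - sqrt(x^2 + y^2), Inf),
    ifelse(y < 0, hw - abs(x), Inf),
    ifelse(y < 0, y + d, Inf),
    ifelse(y < -(d - rc) & abs(x) > hw - rc,
           rc - sqrt((abs(x) - (hw - rc))^2 + (y + (d - rc))^2), Inf)
  )
  apply(cand, 1, min)
}

#' Build the voxelized phantom
#'
#' Rasterizes a [phantom_spec()] onto its grid. Voxel membership is decided
#' by a voxel-centre-inside-surface test. Returns co-registered activity,
#' attenuation and integer label volumes (0 = outside, 1 = background
#' compartment, sphere labels >= 2).
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `spect_phantom`: list with `activity`, `mu`,
#'   `labels` (3-D arrays) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid; vx <- spec$voxel
  ax <- grid_axes(g, vx)
  fov <- g * vx
  need <- c(2 * spec$body$half_width, spec$body$top_radius + spec$body$depth)
  if (fov[1] < need[1] || fov[2] < need[2]) {
    abort("grid too small to contain the body outline")
  }
  sp <- spec$spheres
  if (nrow(sp) > 0) {
    rads <- sp$diameter_mm / 2
    # spheres must sit fully inside the body (checked at axis extremes)
    for (i in seq_len(nrow(sp))) {
      px <- sp$x[i] + c(-1, 1, 0, 0) * rads[i]
      py <- sp$y[i] + c(0, 0, -1, 1) * rads[i]
      if (!all(inside_body_2d(px, py, spec$body)) ||
          abs(sp$z[i]) + rads[i] > spec$body$length / 2) {
        abort(sprintf("sphere %d (%.0f mm) extends outside the body",
                      sp$label[i], sp$diameter_mm[i]))
      }
    }
    if (nrow(sp) > 1) {
      dmat <- as.matrix(stats::dist(sp[, c("x", "y", "z")]))
      lim <- outer(rads, rads, "+")
      diag(dmat) <- Inf
      if (any(dmat < lim)) abort("spheres overlap")
    }
  }

  body2d <- outer(ax[[1]], ax[[2]],
                  function(x, y) inside_body_2d(x, y, spec$body))
  inz <- abs(ax[[3]]) <= spec$body$length / 2
  labels <- array(0L, g)
  body3d <- array(as.vector(body2d), g) &
    rep(inz, each = g[1] * g[2])
  labels[body3d] <- 1L

  mu <- array(0, g)
  mu[body3d] <- spec$mu_fill

  if (isTRUE(spec$lung_insert)) {
    r2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
    cyl <- array(as.vector(r2 <= spec$lung_radius^2), g) & body3d
    labels[cyl] <- 0L
    mu[cyl] <- spec$mu_lung
  }

  dx2 <- lapply(seq_len(nrow(sp)), function(i) {
    list((ax[[1]] - sp$x[i])^2, (ax[[2]] - sp$y[i])^2, (ax[[3]] - sp$z[i])^2)
  })
  for (i in seq_len(nrow(sp))) {
    d2 <- outer(outer(dx2[[i]][[1]], dx2[[i]][[2]], "+"), dx2[[i]][[3]], "+")
    m <- d2 <= (sp$diameter_mm[i] / 2)^2
    labels[m] <- sp$label[i]
  }

  activity <- array(0, g)
  activity[labels == 1L] <- spec$background_conc
  for (i in seq_len(nrow(sp))) {
    activity[labels == sp$label[i]] <- spec$sphere_conc
  }

  structure(list(activity = activity, mu = mu, labels = labels, spec = spec),
            class = "spect_phantom")
}

#' @export
print.spect_phantom <- function(x, ...) {
  print(x$spec)
  vv <- prod(x$spec$voxel) / 1000
  cat(sprintf("  total activity %.3f MBq over %.2f L\n",
              sum(x$activity) * vv, sum(x$labels > 0) * vv / 1000))
  invisible(x)
}

#' Radioactive-decay calibration of an activity concentration
#'
#' Scales a concentration measured at calibration time to the time of
#' acquisition: `conc * 2^(-elapsed / half_life)`.
#'
#' @param concentration Activity concentration (MBq/ml), vectorized.
#' @param elapsed Hours elapsed since calibration (>= 0).
#' @param half_life Isotope half-life in hours; default Tc-99m (6.0058 h).
#' @return The decay-corrected concentration (MBq/ml).
#' @export
decay_correct <- function(concentration, elapsed,
                          half_life = TC99M_HALF_LIFE_H) {
  if (any(elapsed < 0)) abort("elapsed must be >= 0")
  if (any(half_life <= 0)) abort("half_life must be > 0")
  concentration * 2^(-elapsed / half_life)
}

#' Ground-truth sphere VOI masks
#'
#' One boolean mask per hot sphere, taken from the phantom's label volume
#' (the digital analogue of CT-guided inner-edge delineation).
#'
#' @param phantom A `spect_phantom`.
#' @return Named list (names = sphere labels) of logical 3-D arrays;
#'   empty list for a phantom without spheres.
#' @export
voi_masks <- function(phantom) {
  stopifnot(inherits(phantom, "spect_phantom"))
  sp <- phantom$spec$spheres
  out <- lapply(seq_len(nrow(sp)), function(i) {
    phantom$labels == sp$label[i]
  })
  names(out) <- as.character(sp$label)
  out
}
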