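# Rotation-based system model shared by the simulator and the OSEM engine:
# for each view the volume is rotated in-plane (sparse bilinear operator),
# attenuated along the ray axis (Beer-Lambert, cumulative to the detector),
# blurred with a depth-dependent Gaussian PSF, and summed onto the detector.
# Backprojection is the exact transpose of each step, so <Ax, r> = <x, A'r>
# to floating-point accuracy -- the adjoint pairing OSEM relies on.

# Symmetric Toeplitz Gaussian convolution matrix (kernel normalized to unit
# sum; symmetric so the blur is its own transpose). sigma in pixel units.
# The kernel integrates the Gaussian over each pixel bin, so sub-pixel
# widths still blur slightly instead of degenerating to the identity.
gauss_toeplitz <- function(n, sigma) {
  if (sigma <= 1e-8) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  edges <- seq(-half - 0.5, half + 0.5)
  k <- diff(pnorm(edges, sd = sigma))
  k <- k / sum(k)
  G <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1 & j <= n
    G[cbind(idx[ok], j[ok])] <- G[cbind(idx[ok], j[ok])] + k[off + half + 1]
  }
  G
}

# Sparse bilinear rotation operator on an nx x ny in-plane grid (mm spacing
# dx, dy), mapping vec(plane) -> vec(rotated plane). Out-of-grid source
# weights are dropped (the body always fits the square FOV, so no mass from
# the object is lost).
rotation_operator <- function(nx, ny, dx, dy, theta_deg) {
  th <- theta_deg * pi / 180
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dy
  X <- rep(xs, times = ny)
  Y <- rep(ys, each = nx)
  sx <- cos(th) * X - sin(th) * Y
  sy <- sin(th) * X + cos(th) * Y
  fx <- sx / dx + (nx + 1) / 2
  fy <- sy / dy + (ny + 1) / 2
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  tgt <- seq_len(nx * ny)
  ii <- c(i0, i0 + 1, i0, i0 + 1)
  jj <- c(j0, j0, j0 + 1, j0 + 1)
  ww <- c((1 - ax) * (1 - ay), ax * (1 - ay), (1 - ax) * ay, ax * ay)
  tt <- rep(tgt, 4)
  ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & ww > 0
  Matrix::sparseMatrix(i = tt[ok], j = ii[ok] + (jj[ok] - 1) * nx,
                       x = ww[ok], dims = c(nx * ny, nx * ny))
}

# Build the per-study projector. grid = c(nx, ny, nz), voxel in mm,
# angles in degrees; psf = list(intercept, slope) in mm / mm-per-mm or NULL;
# mu = attenuation array (cm^-1) or NULL; psf_band groups depth planes that
# share one blur matrix (FWHM varies by < band * voxel * slope within a
# band, a sub-voxel quantization of the depth dependence).
make_projector <- function(grid, voxel, angles_deg, psf = NULL, mu = NULL,
                           psf_band = 4L) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  nxy <- nx * ny
  W <- lapply(angles_deg, function(a) rotation_operator(nx, ny, voxel[1],
                                                        voxel[2], a))
  Wt <- lapply(W, Matrix::t)

  bands <- split(seq_len(ny), ceiling(seq_len(ny) / psf_band))
  blur <- NULL
  if (!is.null(psf)) {
    blur <- lapply(bands, function(js) {
      d <- (ny - mean(js) + 0.5) * voxel[2]   # depth to detector at +y, mm
      sigma <- fwhm_to_sigma(psf$intercept + psf$slope * d)
      list(Gx = gauss_toeplitz(nx, sigma / voxel[1]),
           Gz = gauss_toeplitz(nz, sigma / voxel[3]))
    })
  }

  att_cache <- new.env(parent = emptyenv())
  att_view <- function(v) {
    key <- as.character(v)
    if (!is.null(att_cache[[key]])) return(att_cache[[key]])
    murot <- array(as.matrix(W[[v]] %*% matrix(mu, nxy, nz)), c(nx, ny, nz))
    att <- array(0, c(nx, ny, nz))
    cum <- matrix(0, nx, nz)
    dy_cm <- voxel[2] / 10
    for (j in ny:1) {                       # detector at +y (j = ny side)
      mj <- matrix(murot[, j, ], nx, nz)
      att[, j, ] <- exp(-dy_cm * (cum + 0.5 * mj))
      cum <- cum + mj
    }
    att_cache[[key]] <- att
    att
  }

  fp_view <- function(x, v) {
    rot <- array(as.matrix(W[[v]] %*% matrix(x, nxy, nz)), c(nx, ny, nz))
    if (!is.null(mu)) rot <- rot * att_view(v)
    acc <- matrix(0, nx, nz)
    if (is.null(blur)) {
      for (j in seq_len(ny)) acc <- acc + matrix(rot[, j, ], nx, nz)
    } else {
      for (b in seq_along(bands)) {
        S <- matrix(0, nx, nz)
        for (j in bands[[b]]) S <- S + matrix(rot[, j, ], nx, nz)
        acc <- acc + blur[[b]]$Gx %*% S %*% blur[[b]]$Gz
      }
    }
    as.matrix(acc)
  }

  bp_view <- function(r, v) {
    out <- array(0, c(nx, ny, nz))
    if (is.null(blur)) {
      for (j in seq_len(ny)) out[, j, ] <- r
    } else {
      for (b in seq_along(bands)) {
        P <- as.matrix(blur[[b]]$Gx %*% r %*% blur[[b]]$Gz)
        for (j in bands[[b]]) out[, j, ] <- P
      }
    }
    if (!is.null(mu)) out <- out * att_view(v)
    array(as.matrix(Wt[[v]] %*% matrix(out, nxy, nz)), c(nx, ny, nz))
  }

  list(grid = grid, voxel = voxel, angles = angles_deg,
       n_views = length(angles_deg),
       fp_view = fp_view, bp_view = bp_view)
}
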