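# Shared fixtures: all built in code at test time.

# Desk-scale study phantom, built once per test run.
desk_phantom <- local({
  cache <- NULL
  function(tb = 32) {
    if (is.null(cache)) cache <<- build_phantom(sim_phantom_spec(tb))
    cache
  }
})

# Minimal hand-built phantom container for projector physics tests.
manual_phantom <- function(activity, mu, voxel) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  labels <- array(0L, dim(activity))
  labels[activity > 0 | mu > 0] <- 1L
  structure(list(activity = activity, mu = mu, labels = labels,
                 spec = list(grid = dim(activity), voxel = voxel,
                             spheres = tibble::tibble(label = integer(),
                                                      diameter_mm = numeric(),
                                                      x = numeric(),
                                                      y = numeric(),
                                                      z = numeric()))),
            class = "spect_phantom")
}

# Dense-matrix operator wrappers: expose an arbitrary nonnegative system
# matrix A through the same interface the OSEM engine uses, with one "view"
# per matrix row.
matrix_ops <- function(A) {
  list(
    fp = function(x, rows) as.vector(A[rows, , drop = FALSE] %*% x),
    bp = function(r, rows) as.vector(t(A[rows, , drop = FALSE]) %*% r),
    y_split = function(y, subsets) lapply(subsets, function(rows) y[rows])
  )
}

# Independent brute-force EM oracle: one full multiplicative EM update,
# x <- x / (A' 1) * A' (y / (A x)).
em_oracle_step <- function(x, A, y) {
  f <- as.vector(A %*% x)
  ratio <- ifelse(f > 0, y / f, 0)
  u <- as.vector(t(A) %*% ratio)
  s <- as.vector(t(A) %*% rep(1, nrow(A)))
  x * (u / s)
}

# Run the package engine as plain MLEM on a dense system.
run_mlem_dense <- function(A, y, x0, n_iter, record = NULL) {
  ops <- matrix_ops(A)
  subs <- list(seq_len(nrow(A)))
  spectrc:::osem_core(x0, n_iter, subs, ops$fp, ops$bp,
                      ops$y_split(y, subs), record = record)
}

# Minimal projection_set wrapper around given count arrays.
manual_projection_set <- function(photopeak, scatterwin = photopeak * 0,
                                  time = 120) {
  cfg <- acquisition_config(n_views = dim(photopeak)[3],
                            time_per_frame = time)
  structure(list(photopeak = photopeak, scatterwin = scatterwin,
                 truth = photopeak, view_angles = cfg$view_angles,
                 config = cfg, phantom_spec = NULL, noise = TRUE),
            class = "projection_set")
}
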