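# internal helpers: grids, affines, small validation utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

#' Voxel-to-world affine for a centred grid
#'
#' Builds the 4x4 voxel-to-world matrix used throughout the package:
#' isotropic scaling by the voxel size with the world origin at the grid
#' centre (RAS-style axes). Voxel indices are 0-based in the affine
#' convention, as in the NIfTI standard.
#'
#' @param dims integer vector of 3 grid dimensions.
#' @param voxel voxel edge length in mm.
#' @return a 4x4 numeric matrix.
#' @keywords internal
vox_affine <- function(dims, voxel) {
  aff <- diag(c(rep(voxel, 3L), 1))
  aff[1:3, 4] <- -voxel * (dims - 1) / 2
  aff
}

# axis coordinate vectors (world mm) of voxel centres
axis_coords <- function(dims, voxel) {
  lapply(seq_len(3L), function(a) voxel * (seq_len(dims[a]) - (dims[a] + 1) / 2))
}

# n x 3 matrix of world coordinates for every voxel, column-major order
grid_world <- function(dims, voxel) {
  ax <- axis_coords(dims, voxel)
  cbind(rep(ax[[1]], times = dims[2] * dims[3]),
        rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
        rep(ax[[3]], each = dims[1] * dims[2]))
}

# world (n x 3) -> fractional 1-based voxel indices under vox_affine()
world_to_ijk <- function(points, affine) {
  inv <- solve(affine)
  ijk0 <- cbind(points, 1) %*% t(inv)
  ijk0[, 1:3, drop = FALSE] + 1
}

ijk_to_world <- function(ijk, affine) {
  w <- cbind(ijk - 1, 1) %*% t(affine)
  w[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a), dim(b))
}

# deterministic per-subject seed stream below 2^31
subject_seed <- function(master_seed, subject_index, stream = 0L) {
  s <- (as.double(master_seed %% 1000003L) * 1009 +
          as.double(subject_index) * 9973 +
          as.double(stream) * 524287) %% 2147483646
  as.integer(s) + 1L
}

# smooth low-frequency cosine field over the FOV, parameterised so it can
# be evaluated consistently at arbitrary world points (B1+ and receive
# fields). The normalising peak is fixed at draw time on a dense probe grid
# so that coarse- and fine-grid evaluations see the same field; values are
# clamped to 1 +/- amplitude.
cosfield_draw <- function(amplitude, fov, n_modes = 3L,
                          freq_range = c(0.2, 0.7)) {
  p <- list(freq = matrix(runif(n_modes * 3L, freq_range[1], freq_range[2]),
                          n_modes, 3L),
            phase = runif(n_modes, 0, 2 * pi),
            coef = rnorm(n_modes),
            amplitude = amplitude, fov = fov, scale = 1)
  probe <- as.matrix(expand.grid(seq(-fov[1] / 2, fov[1] / 2, length.out = 21),
                                 seq(-fov[2] / 2, fov[2] / 2, length.out = 21),
                                 seq(-fov[3] / 2, fov[3] / 2, length.out = 21)))
  peak <- max(abs(cosfield_raw(p, probe)))
  p$scale <- if (peak > 0) amplitude / peak else 0
  p
}

cosfield_raw <- function(params, points) {
  f <- rep(0, nrow(points))
  for (m in seq_along(params$coef)) {
    arg <- 2 * pi * (points %*% (params$freq[m, ] / params$fov)) + params$phase[m]
    f <- f + params$coef[m] * cos(arg)
  }
  as.vector(f)
}

cosfield_eval <- function(params, points) {
  if (is.null(params) || params$amplitude == 0) return(rep(1, nrow(points)))
  f <- cosfield_raw(params, points) * params$scale
  1 + pmin(pmax(f, -params$amplitude), params$amplitude)
}
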