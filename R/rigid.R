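# rigid world-space transforms and AC-PC reorientation

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @return a `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stopf("rotation must be orthonormal with determinant +1")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform$R), 2, -transform$t)
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return their composition a o b.
#' @export
compose_rigid <- function(a, b)
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_rigid <- function(transform)
  rigid_transform(t(transform$R), -as.vector(t(transform$R) %*% transform$t))

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$R, 6))
  cat(sprintf("  translation: %s mm\n",
              paste(round(x$t, 4), collapse = ", ")))
  invisible(x)
}

#' AC-PC reorientation transform
#'
#' Builds the rigid transform that maps the midpoint of the anterior and
#' posterior commissure landmarks to the world origin and the AC-to-PC
#' direction onto the -y world axis (the convention used before manual
#' habenula delineation; the inverse carries drawn ROIs back to native
#' space). The rotation is the minimal rotation between the two
#' directions.
#'
#' @param ac,pc AC and PC landmark coordinates (world mm).
#' @return a [rigid_transform()].
#' @examples
#' tf <- acpc_transform(c(0, 12, -3), c(0, -12, -3))
#' apply_rigid(tf, rbind(c(0, 12, -3), c(0, -12, -3)))
#' @export
acpc_transform <- function(ac, pc) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  d <- pc - ac
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stopf("AC and PC landmarks coincide")
  u <- d / len
  v <- c(0, -1, 0)
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(u * v)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(-1, -1, 1))  # pi about z
  } else {
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  mid <- (ac + pc) / 2
  rigid_transform(R, -as.vector(R %*% mid))
}

#' Resample a volume under a rigid transform
#'
#' Returns the volume re-gridded on its own grid after applying the
#' transform: the output value at world position x is the input value at
#' `transform^-1(x)`. Binary masks should use nearest-neighbour
#' interpolation, continuous maps trilinear.
#'
#' @param volume 3D array.
#' @param transform a [rigid_transform()].
#' @param affine voxel-to-world matrix of the grid.
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @return resampled array of the same dimensions.
#' @export
resample <- function(volume, transform, affine,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dims <- dim(volume)
  voxel <- affine[1, 1]
  pts <- grid_world(dims, voxel)
  src <- apply_rigid(invert_rigid(transform), pts)
  out <- resample_world(volume, affine, src, method = interpolation)
  array(out, dims)
}
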