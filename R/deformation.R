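# Smooth invertible deformations between subject and template space.
#
# A deformation is a sum of K Gaussian displacement bumps,
#   psi(x) = x + sum_k a_k exp(-|x - c_k|^2 / (2 s^2)),
# scaled so the maximum displacement equals the requested amplitude. The
# forward direction maps subject space to template space; the inverse is
# evaluated by fixed-point iteration (contraction for the amplitudes and
# bump widths used here) and verified by a round-trip tolerance.

deform_identity <- function() {
  structure(list(centers = matrix(0, 0, 3), amps = matrix(0, 0, 3),
                 sigma = 1, scale = 0), class = "hab_deformation")
}

# draws from the current RNG stream
deform_draw <- function(amplitude, fov, n_bumps = 6L, sigma = 7) {
  centers <- cbind(runif(n_bumps, -0.3 * fov[1], 0.3 * fov[1]),
                   runif(n_bumps, -0.3 * fov[2], 0.3 * fov[2]),
                   runif(n_bumps, -0.3 * fov[3], 0.3 * fov[3]))
  amps <- matrix(rnorm(n_bumps * 3L, sd = 1), n_bumps, 3L)
  d <- structure(list(centers = centers, amps = amps, sigma = sigma,
                      scale = 1), class = "hab_deformation")
  if (amplitude <= 0) return(deform_identity())
  probe <- as.matrix(expand.grid(seq(-fov[1] / 2, fov[1] / 2, length.out = 17),
                                 seq(-fov[2] / 2, fov[2] / 2, length.out = 17),
                                 seq(-fov[3] / 2, fov[3] / 2, length.out = 17)))
  disp <- deform_displacement(d, probe)
  peak <- max(sqrt(rowSums(disp^2)))
  d$scale <- if (peak > 0) amplitude / peak else 0
  d
}

deform_is_identity <- function(d) nrow(d$centers) == 0L || d$scale == 0

deform_displacement <- function(d, points) {
  disp <- matrix(0, nrow(points), 3L)
  if (deform_is_identity(d)) return(disp)
  for (k in seq_len(nrow(d$centers))) {
    dx <- points[, 1] - d$centers[k, 1]
    dy <- points[, 2] - d$centers[k, 2]
    dz <- points[, 3] - d$centers[k, 3]
    w <- exp(-(dx * dx + dy * dy + dz * dz) / (2 * d$sigma^2))
    disp <- disp + outer(w, d$amps[k, ])
  }
  disp * d$scale
}

# subject -> template
deform_forward <- function(d, points) points + deform_displacement(d, points)

# template -> subject, by fixed-point iteration on x = y - D(x)
deform_inverse <- function(d, points, iter = 30L, tol = 1e-6) {
  if (deform_is_identity(d)) return(points)
  x <- points
  for (i in seq_len(iter)) {
    x_new <- points - deform_displacement(d, x)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol) break
  }
  x
}

# round-trip check: forward then inverse must return within tol_mm
deform_invertible <- function(d, fov, tol_mm) {
  probe <- as.matrix(expand.grid(seq(-fov[1] / 2, fov[1] / 2, length.out = 9),
                                 seq(-fov[2] / 2, fov[2] / 2, length.out = 9),
                                 seq(-fov[3] / 2, fov[3] / 2, length.out = 9)))
  y <- deform_forward(d, probe)
  back <- deform_inverse(d, y)
  max(abs(back - probe)) < tol_mm
}

deform_to_list <- function(d) {
  list(centers = unname(apply(d$centers, 1, c, simplify = FALSE)),
       amps = unname(apply(d$amps, 1, c, simplify = FALSE)),
       sigma = d$sigma, scale = d$scale)
}

deform_from_list <- function(l) {
  if (is.null(l) || length(l$centers) == 0L) return(deform_identity())
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  structure(list(centers = as_mat(l$centers),
                 amps = as_mat(l$amps),
                 sigma = l$sigma, scale = l$scale),
            class = "hab_deformation")
}
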