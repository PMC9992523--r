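# forward simulation of the spoiled multi-echo FLASH acquisition

# Ernst steady-state spoiled FLASH signal with mono-exponential echo
# decay. MT weighting enters as a fractional saturation d of longitudinal
# magnetisation applied once per TR before excitation:
#   S(TE) = c_RX * A * sin(a) * (1-d) * (1-E1) / (1 - (1-d) cos(a) E1)
#           * exp(-TE * R2s),   E1 = exp(-TR * R1), a = f_T * alpha.
flash_signal <- function(A, R1, R2s, tr_s, alpha_rad, d = 0, te_s = 0,
                         c_rx = 1) {
  E1 <- exp(-tr_s * R1)
  c_rx * A * sin(alpha_rad) * (1 - d) * (1 - E1) /
    (1 - (1 - d) * cos(alpha_rad) * E1) * exp(-te_s * R2s)
}

#' Simulate the multi-echo FLASH acquisition for one subject
#'
#' Evaluates the spoiled steady-state FLASH signal voxelwise for each
#' weighting and echo, with the nominal excitation flip angle scaled by
#' the subject's transmit-field fraction f_T and the signal scaled by the
#' receive-sensitivity field. The MT-weighted scan applies the subject's
#' ground-truth MT saturation; by default the *delivered* saturation
#' scales with the local transmit field as
#' `delta * (1 - 0.4 f_T) / (1 - 0.4)` (the dependence that the
#' transmit-bias correction in [compute_mtsat()] inverts; switch off via
#' `phantom_spec(mt_transmit_model = "none")`).
#'
#' Also emits the effective B1+ map (f_T) and the low-resolution
#' receive-calibration pair: the true receive field sampled on an 8 mm
#' grid plus its unit-field companion, emulating the array/body-coil
#' calibration scans whose ratio estimates the net receive sensitivity.
#'
#' @param subject a `subject_truth` from [build_template()] or
#'   [sample_subject()].
#' @param protocol an [mpm_protocol()].
#' @param spec the [phantom_spec()] (controls the MT transmit model).
#' @param calib_voxel_mm voxel size of the receive-calibration pair.
#' @return an `echo_volume_set`: per-weighting 4D echo stacks (signal,
#'   arbitrary units), the protocol, `b1` (f_T map), the coarse
#'   calibration pair with its own affine, and grid metadata.
#' @examples
#' spec <- phantom_spec()
#' vols <- simulate_flash(build_template(spec), mpm_protocol(), spec)
#' dim(vols$stacks$PDw)     # grid dims x 8 echoes
#' @export
simulate_flash <- function(subject, protocol = mpm_protocol(),
                           spec = phantom_spec(), calib_voxel_mm = 8) {
  validate_protocol(protocol)
  dims <- subject$dims
  brain <- subject$label != LBL_BG
  for (p in c("R1", "R2s", "A")) {
    bad <- which(!is.finite(subject[[p]]) | (brain & subject[[p]] < 0))
    if (length(bad))
      stopf("non-finite or negative %s at voxel %d", p, bad[1])
  }

  tr_s <- protocol$T1w$tr_ms / 1000
  delta <- subject$MTsat / 100            # truth stored in percent units
  d_mt <- if (spec$mt_transmit_model == "linear")
    pmin(pmax(delta * (1 - 0.4 * subject$f_T) / (1 - 0.4), 0), 0.99)
  else delta

  stacks <- list()
  for (w in protocol_weightings(protocol)) {
    p <- protocol[[w]]
    a <- subject$f_T * (p$flip_deg * pi / 180)
    d <- if (w == "MTw") d_mt else 0
    s0 <- flash_signal(subject$A, subject$R1, 0, tr_s, a, d = d,
                       c_rx = subject$rx)
    s0[!brain] <- 0
    stack <- array(0, c(dims, length(p$te_ms)))
    for (n in seq_along(p$te_ms))
      stack[, , , n] <- s0 * exp(-(p$te_ms[n] / 1000) * subject$R2s)
    stacks[[w]] <- stack
  }

  fov <- dims * subject$voxel
  # calibration scans cover more than the imaging FOV (two-voxel margin)
  # so upsampling to the map grid never extrapolates
  cal_dims <- pmax(2L, as.integer(ceiling(fov / calib_voxel_mm)) + 4L)
  cal_affine <- vox_affine(cal_dims, calib_voxel_mm)
  cal_pts <- grid_world(cal_dims, calib_voxel_mm)
  # map calibration-grid world coords through the (shared) world frame
  rx_cal <- array(cosfield_eval(subject$rx_params, cal_pts), cal_dims)

  structure(list(stacks = stacks, protocol = protocol,
                 b1 = subject$f_T,
                 rx_cal = list(array_coil = rx_cal,
                               body_coil = array(1, cal_dims),
                               affine = cal_affine, dims = cal_dims,
                               voxel = calib_voxel_mm),
                 affine = subject$affine, voxel = subject$voxel,
                 dims = dims, noise_sigma = 0),
            class = "echo_volume_set")
}

#' @export
print.echo_volume_set <- function(x, ...) {
  cat("Simulated multi-echo FLASH volumes\n")
  for (w in names(x$stacks))
    cat(sprintf("  %s: %d echoes on grid %s\n", w, dim(x$stacks[[w]])[4],
                paste(x$dims, collapse = "x")))
  cat(sprintf("  noise sigma: %g\n", x$noise_sigma))
  invisible(x)
}

#' Add measurement noise to simulated volumes
#'
#' Applies Rician noise to the magnitude echo images: each voxel becomes
#' the magnitude of the complex signal plus independent zero-mean
#' Gaussian noise of SD `sigma` on both quadrature channels. With
#' `phantom_spec(noise_model = "gaussian")` plain additive Gaussian noise
#' is used instead (useful for estimator oracles). The receive-calibration
#' pair receives relative Gaussian noise of SD `spec$calib_noise`.
#'
#' `sigma` is `spec$noise_sigma` if set, otherwise derived as
#' (mean brain signal of the first PD-weighted echo) / `spec$target_snr`.
#' With `sigma == 0` the input is returned unchanged.
#'
#' @param volumes an `echo_volume_set` from [simulate_flash()].
#' @param spec the [phantom_spec()] (noise model and level).
#' @param seed integer seed; the operation is reproducible.
#' @return the `echo_volume_set` with noisy stacks and `noise_sigma` set.
#' @export
add_noise <- function(volumes, spec = phantom_spec(), seed = 1L) {
  sigma <- spec$noise_sigma
  if (is.null(sigma)) {
    e1 <- volumes$stacks$PDw[, , , 1]
    sig <- mean(e1[e1 > 0])
    sigma <- sig / spec$target_snr
  }
  if (sigma < 0) stopf("noise sigma must be >= 0")
  if (sigma == 0) return(volumes)
  set.seed(seed)
  for (w in names(volumes$stacks)) {
    s <- volumes$stacks[[w]]
    if (spec$noise_model == "rician") {
      volumes$stacks[[w]] <- array(
        sqrt((s + rnorm(length(s), 0, sigma))^2 +
               rnorm(length(s), 0, sigma)^2), dim(s))
    } else {
      volumes$stacks[[w]] <- s + array(rnorm(length(s), 0, sigma), dim(s))
    }
  }
  if (!is.null(volumes$rx_cal) && spec$calib_noise > 0) {
    for (v in c("array_coil", "body_coil")) {
      cal <- volumes$rx_cal[[v]]
      volumes$rx_cal[[v]] <- cal +
        array(rnorm(length(cal), 0, spec$calib_noise * mean(cal)), dim(cal))
    }
  }
  volumes$noise_sigma <- sigma
  volumes
}
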