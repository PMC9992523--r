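#' Per-tissue ground-truth parameter distributions
#'
#' Each tissue class carries the cohort mean and between-subject standard
#' deviation of its four quantitative parameters: R1 (1/s), R2* (1/s), PD
#' (percent units, water content) and MTsat (percent units). The habenula
#' row is calibrated to published in-vivo 3T cohort statistics
#' (R1 0.86 +/- 0.03 1/s, R2* 19.11 +/- 1.87 1/s, PD 76.21 +/- 1.52 p.u.,
#' MTsat 1.05 +/- 0.08 p.u.); WM, thalamic GM and CSF use
#' literature-typical 3T values.
#'
#' @param name tissue class name, one of `"WM"`, `"GM"`, `"CSF"`,
#'   `"habenula"`.
#' @param R1_mean,R1_sd longitudinal relaxation rate (1/s).
#' @param R2s_mean,R2s_sd effective transverse relaxation rate (1/s).
#' @param PD_mean,PD_sd proton density (p.u., at most 100).
#' @param MTsat_mean,MTsat_sd MT saturation (p.u.).
#' @return a `tissue_params` object (named list).
#' @export
tissue_params <- function(name, R1_mean, R1_sd, R2s_mean, R2s_sd,
                          PD_mean, PD_sd, MTsat_mean, MTsat_sd) {
  name <- match.arg(name, c("WM", "GM", "CSF", "habenula"))
  check_number(R1_mean, "R1_mean", lower = 1e-6)
  check_number(R2s_mean, "R2s_mean", lower = 1e-6)
  check_number(PD_mean, "PD_mean", lower = 1e-6, upper = 100)
  check_number(MTsat_mean, "MTsat_mean", lower = 0)
  for (s in c(R1_sd, R2s_sd, PD_sd, MTsat_sd))
    check_number(s, "sd", lower = 0)
  structure(list(name = name,
                 R1_mean = R1_mean, R1_sd = R1_sd,
                 R2s_mean = R2s_mean, R2s_sd = R2s_sd,
                 PD_mean = PD_mean, PD_sd = PD_sd,
                 MTsat_mean = MTsat_mean, MTsat_sd = MTsat_sd),
            class = "tissue_params")
}

default_tissue_params <- function() {
  list(
    WM = tissue_params("WM", 1.10, 0.03, 21.0, 1.0, 69.0, 1.0, 1.90, 0.10),
    GM = tissue_params("GM", 0.70, 0.02, 16.0, 1.0, 83.0, 1.0, 0.90, 0.06),
    CSF = tissue_params("CSF", 0.25, 0.01, 1.5, 0.3, 100.0, 0.0, 0.0, 0.0),
    habenula = tissue_params("habenula", 0.86, 0.03, 19.11, 1.87,
                             76.21, 1.52, 1.05, 0.08)
  )
}

#' Phantom cohort specification
#'
#' Defines the synthetic cohort: grid geometry, habenula volume
#' distribution, per-tissue parameter distributions, inter-subject
#' deformation amplitude, field-inhomogeneity amplitudes, noise level and
#' the master seed from which everything is reproducible.
#'
#' Defaults emulate the study conditions: 0.8 mm isotropic voxels, 26
#' subjects, mean habenula volume 19.26 mm^3 with SD 2.03 mm^3, target
#' SNR 100 on the first PD-weighted echo. The default grid is a
#' 48 x 64 x 48 thalamic field of view rather than a whole-head matrix.
#'
#' @param grid_dims integer vector of 3 grid dimensions (each >= 16).
#' @param voxel_size isotropic voxel edge in mm.
#' @param cohort_size number of subjects.
#' @param habenula_volume_mean,habenula_volume_sd per-side habenula volume
#'   distribution (mm^3) across subjects.
#' @param tissue_params list of [tissue_params()] objects named WM, GM,
#'   CSF, habenula.
#' @param deformation_amplitude maximum displacement (mm) of the smooth
#'   random subject-to-template deformation.
#' @param misalignment_sd per-axis SD (mm) of the residual rigid
#'   misalignment applied when warping to template space.
#' @param noise_sigma Gaussian channel noise SD in signal units, or `NULL`
#'   to derive it from `target_snr`.
#' @param target_snr signal-to-noise ratio used to derive `noise_sigma`
#'   from the mean brain signal of the first PD-weighted echo.
#' @param noise_model `"rician"` (magnitude of complex Gaussian noise) or
#'   `"gaussian"`.
#' @param ft_amplitude maximum deviation of the transmit-field fraction
#'   f_T from 1 (default 0.1, i.e. f_T in \[0.9, 1.1\]).
#' @param rx_amplitude maximum deviation of the receive-sensitivity field
#'   from 1 (default 0.3, i.e. c_RX in \[0.7, 1.3\]).
#' @param calib_noise relative noise SD applied to the low-resolution
#'   receive-calibration volumes by [add_noise()].
#' @param mt_transmit_model how the delivered MT saturation depends on the
#'   local transmit field: `"linear"` (saturation scales as
#'   (1 - 0.4 f_T)/(1 - 0.4), the dependence the MTsat transmit-bias
#'   correction inverts) or `"none"`.
#' @param master_seed integer master seed.
#' @return a `phantom_spec` object.
#' @examples
#' spec <- phantom_spec(cohort_size = 2)
#' spec$habenula_volume_mean
#' @export
phantom_spec <- function(grid_dims = c(48L, 64L, 48L),
                         voxel_size = 0.8,
                         cohort_size = 26L,
                         habenula_volume_mean = 19.26,
                         habenula_volume_sd = 2.03,
                         tissue_params = default_tissue_params(),
                         deformation_amplitude = 1.5,
                         misalignment_sd = 0.4,
                         noise_sigma = NULL,
                         target_snr = 100,
                         noise_model = c("rician", "gaussian"),
                         ft_amplitude = 0.1,
                         rx_amplitude = 0.3,
                         calib_noise = 0.005,
                         mt_transmit_model = c("linear", "none"),
                         master_seed = 1L) {
  if (length(grid_dims) != 3L || any(grid_dims < 16))
    stopf("grid_dims must be 3 values, all >= 16")
  check_number(voxel_size, "voxel_size", lower = 1e-6)
  check_number(cohort_size, "cohort_size", lower = 1)
  check_number(habenula_volume_mean, "habenula_volume_mean", lower = 1e-6)
  check_number(habenula_volume_sd, "habenula_volume_sd", lower = 0)
  check_number(deformation_amplitude, "deformation_amplitude", lower = 0)
  check_number(misalignment_sd, "misalignment_sd", lower = 0)
  if (!is.null(noise_sigma)) check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(target_snr, "target_snr", lower = 1e-6)
  check_number(ft_amplitude, "ft_amplitude", lower = 0, upper = 0.5)
  check_number(rx_amplitude, "rx_amplitude", lower = 0, upper = 0.9)
  stopifnot(all(c("WM", "GM", "CSF", "habenula") %in% names(tissue_params)))
  structure(list(grid_dims = as.integer(grid_dims),
                 voxel_size = voxel_size,
                 cohort_size = as.integer(cohort_size),
                 habenula_volume_mean = habenula_volume_mean,
                 habenula_volume_sd = habenula_volume_sd,
                 tissue_params = tissue_params,
                 deformation_amplitude = deformation_amplitude,
                 misalignment_sd = misalignment_sd,
                 noise_sigma = noise_sigma,
                 target_snr = target_snr,
                 noise_model = match.arg(noise_model),
                 ft_amplitude = ft_amplitude,
                 rx_amplitude = rx_amplitude,
                 calib_noise = calib_noise,
                 mt_transmit_model = match.arg(mt_transmit_model),
                 master_seed = as.integer(master_seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom cohort spec: %d subjects, grid %s @ %g mm\n",
              x$cohort_size, paste(x$grid_dims, collapse = "x"),
              x$voxel_size))
  cat(sprintf("  habenula volume %g +/- %g mm^3; deformation <= %g mm\n",
              x$habenula_volume_mean, x$habenula_volume_sd,
              x$deformation_amplitude))
  cat(sprintf("  noise: %s, %s; master seed %d\n", x$noise_model,
              if (is.null(x$noise_sigma))
                sprintf("target SNR %g", x$target_snr)
              else sprintf("sigma %g", x$noise_sigma),
              x$master_seed))
  invisible(x)
}
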