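# template-space analysis: warping, averaging, probability atlas,
# threshold sweep

#' Warp a subject's maps and masks to template space
#'
#' Applies the subject's stored ground-truth subject-to-template
#' deformation, composed with a seeded random rigid perturbation
#' (per-axis translation SD `misalignment_sd`, standing in for residual
#' registration error of the normalisation algorithm), then smooths with
#' an isotropic Gaussian of `smoothing_fwhm` mm FWHM. Continuous maps are
#' interpolated trilinearly; binary masks nearest-neighbour and then
#' carried as weight images (values in 0..1 after smoothing).
#'
#' @param subject a `subject_truth` (provides the deformation and masks).
#' @param maps named list of native-space map volumes to warp (may be
#'   NULL entries).
#' @param misalignment_sd per-axis translation SD in mm.
#' @param smoothing_fwhm Gaussian FWHM in mm (0 disables smoothing).
#' @param seed integer seed for the perturbation draw.
#' @param gm_prob optional native GM probability volume to warp along.
#' @return list with `maps` (warped maps), `hab_weight` (habenula weight
#'   image), `gm` (warped GM probability or NULL), `shift` (the drawn
#'   perturbation).
#' @export
warp_to_template <- function(subject, maps, misalignment_sd = 0.4,
                             smoothing_fwhm = 0.8, seed = 1L,
                             gm_prob = NULL) {
  if (is.null(subject$deformation)) stopf("subject has no stored deformation")
  if (smoothing_fwhm < 0) stopf("smoothing_fwhm must be >= 0")
  set.seed(seed)
  shift <- if (misalignment_sd > 0) rnorm(3, 0, misalignment_sd) else c(0, 0, 0)

  dims <- subject$dims; voxel <- subject$voxel
  pts <- grid_world(dims, voxel)
  # template voxel centre -> (perturbed) subject-space source point
  src <- deform_inverse(subject$deformation,
                        sweep(pts, 2, -shift))
  ijk <- world_to_ijk(src, subject$affine)

  wmap <- function(vol, method) {
    if (is.null(vol)) return(NULL)
    out <- array(sample_volume_at(vol, ijk, method = method), dims)
    smooth_gaussian(out, smoothing_fwhm, voxel)
  }
  warped_maps <- lapply(maps, wmap, method = "trilinear")
  hab <- (subject$hab_left | subject$hab_right) + 0
  hab_w <- wmap(hab, "nearest")
  gm_w <- if (!is.null(gm_prob)) wmap(gm_prob, "trilinear") else NULL
  list(maps = warped_maps, hab_weight = hab_w, gm = gm_w, shift = shift)
}

#' Voxelwise average of warped cohort maps
#'
#' @param warped_maps list (one per subject) of map volumes on a common
#'   template grid.
#' @return the voxelwise arithmetic mean.
#' @export
average_maps <- function(warped_maps) {
  warped_maps <- Filter(Negate(is.null), warped_maps)
  if (!length(warped_maps)) stopf("no maps to average")
  d <- dim(warped_maps[[1]])
  for (m in warped_maps)
    if (!identical(dim(m), d)) stopf("grid mismatch across subjects")
  Reduce(`+`, warped_maps) / length(warped_maps)
}

#' Habenula probability atlas
#'
#' Voxelwise mean of the warped (possibly smoothed) habenula mask weight
#' images: the estimated probability that a template voxel lies within
#' the habenula across the cohort.
#'
#' @param mask_weights list of warped habenula weight volumes.
#' @return a `probability_atlas`: the probability volume with attributes
#'   `n_subjects`, `maximum` and `n_at_maximum` (count of voxels
#'   attaining the maximum within 1e-9).
#' @export
probability_map <- function(mask_weights) {
  mask_weights <- Filter(Negate(is.null), mask_weights)
  if (!length(mask_weights)) stopf("need at least one mask")
  atlas <- average_maps(mask_weights)
  atlas <- pmin(pmax(atlas, 0), 1)
  mx <- max(atlas)
  structure(atlas, class = c("probability_atlas", class(atlas)),
            n_subjects = length(mask_weights), maximum = mx,
            n_at_maximum = sum(atlas > mx - 1e-9))
}

#' @export
print.probability_atlas <- function(x, ...) {
  cat(sprintf("Habenula probability atlas: %d subjects, max %.3f at %d voxel(s)\n",
              attr(x, "n_subjects"), attr(x, "maximum"),
              attr(x, "n_at_maximum")))
  invisible(x)
}

#' Fixed grey-matter ROI in template space
#'
#' The comparison ROI for the threshold sweep, kept constant across
#' thresholds: the support of the (non-thresholded) probability atlas is
#' dilated by one voxel, the support removed, and the ring intersected
#' with the thresholded average GM probability.
#'
#' @param atlas a [probability_map()] result.
#' @param gm_avg average GM probability volume in template space.
#' @param threshold GM probability threshold (default 0.9).
#' @param connectivity dilation connectivity (6 or 26).
#' @return logical template-space GM ROI.
#' @export
fixed_gm_roi <- function(atlas, gm_avg, threshold = 0.9, connectivity = 6L) {
  support <- unclass(atlas) > 0
  if (!any(support)) stopf("probability atlas has empty support")
  ring <- dilate_mask(support, connectivity) & !support
  out <- ring & (gm_avg > threshold)
  if (!any(out))
    stopf("fixed GM ROI is empty; review the GM threshold (%g)", threshold)
  out
}

#' CNR versus probability-threshold sweep
#'
#' For each threshold p the habenula ROI is `atlas > p`; the ROI volume
#' and the CNR of each cohort-average map against the fixed GM ROI are
#' recorded. Thresholds whose ROI is empty (or too small for a nonzero
#' SD) are recorded as missing. ROI volume is non-increasing in the
#' threshold by construction.
#'
#' @param avg_maps named list of cohort-average map volumes.
#' @param atlas a [probability_map()] result.
#' @param gm_roi the [fixed_gm_roi()] mask.
#' @param thresholds strictly increasing probabilities in (0, 1).
#' @param voxel_size voxel edge in mm.
#' @return a `sweep_result` data.frame: `threshold`, `roi_vol_mm3`, one
#'   `cnr_<map>` column per map.
#' @export
threshold_sweep <- function(avg_maps, atlas, gm_roi,
                            thresholds = seq(0.05, 0.95, by = 0.05),
                            voxel_size = 0.8) {
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0))
    stopf("thresholds must be strictly increasing within (0, 1)")
  avg_maps <- Filter(Negate(is.null), avg_maps)
  a <- unclass(atlas)
  rows <- lapply(thresholds, function(p) {
    roi <- a > p
    row <- data.frame(threshold = p, roi_vol_mm3 = sum(roi) * voxel_size^3)
    for (m in names(avg_maps)) {
      cnr <- if (!any(roi)) NA_real_ else tryCatch(
        compute_cnr(avg_maps[[m]], roi, gm_roi, map_name = m)$cnr,
        error = function(e) NA_real_)
      row[[paste0("cnr_", m)]] <- cnr
    }
    row
  })
  out <- do.call(rbind, rows)
  if (all(out$roi_vol_mm3 == 0))
    stopf("all thresholds give an empty habenula ROI")
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
plot.sweep_result <- function(x, ...) {
  cols <- grep("^cnr_", names(x), value = TRUE)
  ylim <- range(unlist(x[cols]), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$threshold), ylim = ylim,
                 xlab = "habenula probability threshold", ylab = "CNR", ...)
  for (i in seq_along(cols))
    graphics::lines(x$threshold, x[[cols[i]]], col = i, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", legend = sub("^cnr_", "", cols),
                   col = seq_along(cols), lwd = 2, bty = "n")
  invisible(x)
}
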