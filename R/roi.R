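# ROI statistics and habenula volumetry

#' ROI statistics of a quantitative map
#'
#' Arithmetic mean and standard deviation over in-mask voxels, voxel
#' count and ROI volume. The SD is the population SD (divide by n) by
#' default, matching descriptive use; `sd_type = "sample"` divides by
#' n - 1.
#'
#' @param map 3D array.
#' @param mask logical 3D array of the same dimensions.
#' @param voxel_size voxel edge (mm) for the volume.
#' @param map_name label carried into the output.
#' @param sd_type `"population"` or `"sample"`.
#' @return one-row data.frame: `map`, `mean`, `sd`, `n_voxels`,
#'   `volume_mm3`.
#' @examples
#' m <- array(1:27, c(3, 3, 3))
#' roi_stats(m, m > 20, voxel_size = 0.8)
#' @export
roi_stats <- function(map, mask, voxel_size = 1, map_name = "",
                      sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!identical(dim(map), dim(mask))) stopf("map and mask grids differ")
  n <- sum(mask)
  if (n == 0L) stopf("empty ROI mask")
  v <- map[mask]
  v <- v[is.finite(v)]
  if (!length(v)) stopf("ROI contains no finite map values")
  mu <- mean(v)
  s <- if (length(v) > 1) {
    ss <- sqrt(sum((v - mu)^2) / length(v))
    if (sd_type == "sample") ss * sqrt(length(v) / (length(v) - 1)) else ss
  } else 0
  data.frame(map = map_name, mean = mu, sd = s, n_voxels = n,
             volume_mm3 = n * voxel_size^3, stringsAsFactors = FALSE)
}

#' Habenula volumetry and brain-normalised volume
#'
#' Left, right and mean habenula volumes in mm^3 plus the total habenula
#' volume as a percentage of brain volume. The brain mask is defined from
#' the tissue probabilities: voxels whose summed WM+GM+CSF probability
#' exceeds `threshold` (default reading), or the union of the per-class
#' thresholds with `brain_rule = "per_class"`.
#'
#' @param left_mask,right_mask disjoint logical habenula masks.
#' @param tissue_probs named list of probability volumes with elements
#'   `WM`, `GM`, `CSF`.
#' @param voxel_size voxel edge in mm.
#' @param threshold brain-mask probability threshold (default 0.9).
#' @param brain_rule `"sum"` or `"per_class"`.
#' @return one-row data.frame: `vol_left_mm3`, `vol_right_mm3`,
#'   `vol_mean_mm3`, `vol_norm_pct`, `brain_vol_mm3`.
#' @examples
#' d <- c(16, 16, 16)
#' probs <- list(WM = array(1, d), GM = array(0, d), CSF = array(0, d))
#' l <- array(FALSE, d); l[2, 2, 2] <- TRUE
#' r <- array(FALSE, d); r[4, 4, 4] <- TRUE
#' habenula_volumes(l, r, probs, 0.8)
#' @export
habenula_volumes <- function(left_mask, right_mask, tissue_probs,
                             voxel_size, threshold = 0.9,
                             brain_rule = c("sum", "per_class")) {
  brain_rule <- match.arg(brain_rule)
  if (any(left_mask & right_mask))
    stopf("left and right habenula masks overlap")
  brain <- if (brain_rule == "sum")
    (tissue_probs$WM + tissue_probs$GM + tissue_probs$CSF) > threshold
  else
    tissue_probs$WM > threshold | tissue_probs$GM > threshold |
      tissue_probs$CSF > threshold
  n_brain <- sum(brain)
  if (n_brain == 0L) stopf("empty brain mask at threshold %g", threshold)
  vv <- voxel_size^3
  vl <- sum(left_mask) * vv
  vr <- sum(right_mask) * vv
  data.frame(vol_left_mm3 = vl, vol_right_mm3 = vr,
             vol_mean_mm3 = (vl + vr) / 2,
             vol_norm_pct = 100 * (vl + vr) / (n_brain * vv),
             brain_vol_mm3 = n_brain * vv)
}

# AC-PC reorientation round-trip of a binary mask, as in the manual
# delineation workflow: masks are taken to the reoriented frame and back
# with nearest-neighbour resampling.
acpc_roundtrip_mask <- function(mask, ac, pc, affine) {
  tf <- acpc_transform(ac, pc)
  fwd <- resample(mask + 0, tf, affine, interpolation = "nearest")
  back <- resample(fwd, invert_rigid(tf), affine, interpolation = "nearest")
  back > 0.5
}
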