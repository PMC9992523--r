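# contrast-to-noise ratio between habenula and surrounding grey matter

#' Surrounding grey-matter mask
#'
#' Builds the comparison ROI for the CNR analysis: the habenula mask is
#' dilated by a one-voxel spherical structuring element (6-connected by
#' default: a radius-1 Euclidean ball on the voxel lattice contains only
#' face neighbours), the habenula is removed from the dilation, and the
#' ring is intersected with the thresholded grey-matter probability.
#'
#' @param habenula_mask logical 3D array (nonempty).
#' @param gm_prob grey-matter probability volume.
#' @param threshold GM probability threshold (default 0.9).
#' @param connectivity 6 (default) or 26.
#' @return logical mask of surrounding GM.
#' @examples
#' d <- c(9, 9, 9)
#' hab <- array(FALSE, d); hab[5, 5, 5] <- TRUE
#' sum(surround_gm_mask(hab, array(1, d)))  # 6 face neighbours
#' @export
surround_gm_mask <- function(habenula_mask, gm_prob, threshold = 0.9,
                             connectivity = 6L) {
  if (!any(habenula_mask)) stopf("empty habenula mask")
  ring <- dilate_mask(habenula_mask, connectivity) & !habenula_mask
  out <- ring & (gm_prob > threshold)
  if (!any(out))
    stopf("surrounding-GM mask is empty; review the GM threshold (%g)",
          threshold)
  out
}

#' Contrast-to-noise ratio between habenula and surrounding GM
#'
#' `CNR = (mean(habenula ROI) - mean(GM ROI)) / sd(habenula ROI)`, with
#' the population SD of the habenula ROI as the noise term and the sign
#' preserved (negative when the habenula is hypointense, as on PD maps).
#'
#' @param map quantitative map volume.
#' @param habenula_mask,gm_mask nonempty logical masks.
#' @param map_name label carried into the output.
#' @param subject subject identifier carried into the output.
#' @return one-row data.frame: `subject`, `map`, `hab_mean`, `gm_mean`,
#'   `hab_sd`, `cnr`.
#' @examples
#' m <- array(1, c(5, 5, 5)); m[3, 3, 3] <- 2; m[3, 3, 2] <- 2.2
#' hab <- array(FALSE, dim(m)); hab[3, 3, 2:3] <- TRUE
#' gm <- array(FALSE, dim(m)); gm[3, 3, 4] <- TRUE
#' compute_cnr(m, hab, gm)
#' @export
compute_cnr <- function(map, habenula_mask, gm_mask, map_name = "",
                        subject = NA_integer_) {
  if (!any(habenula_mask)) stopf("empty habenula mask")
  if (!any(gm_mask)) stopf("empty GM mask")
  hv <- map[habenula_mask]; hv <- hv[is.finite(hv)]
  gv <- map[gm_mask]; gv <- gv[is.finite(gv)]
  if (!length(hv) || !length(gv)) stopf("masks contain no finite map values")
  hm <- mean(hv)
  hs <- sqrt(sum((hv - hm)^2) / length(hv))
  if (hs <= 0) stopf("habenula SD is zero: CNR undefined")
  data.frame(subject = subject, map = map_name, hab_mean = hm,
             gm_mean = mean(gv), hab_sd = hs,
             cnr = (hm - mean(gv)) / hs, stringsAsFactors = FALSE)
}

#' Cohort CNR report in native space
#'
#' Computes per-subject, per-map CNR between the habenula and its
#' surrounding GM ring and summarises across the cohort.
#'
#' @param cohort list of subject entries, each a list with `maps` (named
#'   list of map volumes), `hab_mask`, and either `gm_mask` or `gm_prob`
#'   (from which the surround is built via [surround_gm_mask()]).
#' @param gm_threshold GM probability threshold for the surround mask.
#' @param connectivity dilation connectivity (6 or 26).
#' @return data.frame of per-subject rows; attributes `summary` (cohort
#'   mean/SD per map) and `ranking` (maps ordered by mean CNR).
#' @export
native_cnr_report <- function(cohort, gm_threshold = 0.9,
                              connectivity = 6L) {
  if (!length(cohort)) stopf("need at least one subject")
  rows <- list()
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    gm_mask <- e$gm_mask %||%
      surround_gm_mask(e$hab_mask, e$gm_prob, gm_threshold, connectivity)
    for (m in names(e$maps)) {
      if (is.null(e$maps[[m]])) next
      rows[[length(rows) + 1L]] <-
        compute_cnr(e$maps[[m]], e$hab_mask, gm_mask, map_name = m,
                    subject = e$subject %||% i)
    }
  }
  out <- do.call(rbind, rows)
  maps <- unique(out$map)
  summ <- do.call(rbind, lapply(maps, function(m) {
    v <- out$cnr[out$map == m]
    data.frame(map = m, cnr_mean = mean(v),
               cnr_sd = if (length(v) > 1) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  attr(out, "ranking") <- summ$map[order(summ$cnr_mean, decreasing = TRUE)]
  out
}
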