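# Template phantom geometry (world coordinates, mm, origin at grid centre).
#
# Nested desk-scale model of the epithalamic neighbourhood: a WM shell
# (brain ellipsoid), two thalamic GM blocks, a CSF slab for the third
# ventricle between them, and two ellipsoidal habenulae abutting the
# ventricle dorso-posteriorly. Axes: x left-right, y posterior-anterior,
# z inferior-superior.

LBL_BG <- 0L; LBL_WM <- 1L; LBL_GM <- 2L; LBL_CSF <- 3L; LBL_HAB <- 4L
TISSUE_CLASSES <- c("BG", "WM", "GM", "CSF", "habenula")

hab_geometry <- function() {
  list(
    brain_semiaxes = c(16.5, 22.0, 16.5),
    ventricle_halfwidth = c(1.3, 12.0, 9.0),
    thalamus_inner_x = 1.3,
    thalamus_halfwidth = c(11.0, 11.0, 8.0),
    hab_center = c(2.5, -6.0, 4.0),       # right habenula; left mirrored in x
    hab_semiaxes = c(1.30, 2.00, 1.78),
    ac = c(0, 12, -3),
    pc = c(0, -12, -3)
  )
}

# grid-too-small guard: every structure must fit inside the FOV with a
# one-voxel margin
check_geometry_fits <- function(spec) {
  g <- hab_geometry()
  half_fov <- spec$grid_dims * spec$voxel_size / 2 - spec$voxel_size
  extents <- list(
    brain = g$brain_semiaxes,
    `third ventricle` = g$ventricle_halfwidth,
    thalamus = g$thalamus_halfwidth,
    habenula = abs(g$hab_center) + g$hab_semiaxes * 1.6,
    `AC-PC landmarks` = pmax(abs(g$ac), abs(g$pc))
  )
  for (s in names(extents)) {
    if (any(extents[[s]] >= half_fov))
      stopf("grid %s @ %g mm is too small to contain structure '%s'",
            paste(spec$grid_dims, collapse = "x"), spec$voxel_size, s)
  }
  invisible(TRUE)
}

# Evaluate base tissue labels (without habenulae) and the habenula
# ellipsoid metrics at world points (n x 3). The metric is
# sum(((p - c)/semiaxis)^2); the surface is metric == 1.
geom_eval <- function(points) {
  g <- hab_geometry()
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  in_brain <- (x / g$brain_semiaxes[1])^2 + (y / g$brain_semiaxes[2])^2 +
    (z / g$brain_semiaxes[3])^2 <= 1
  v <- g$ventricle_halfwidth
  in_vent <- abs(x) <= v[1] & abs(y) <= v[2] & abs(z) <= v[3]
  t <- g$thalamus_halfwidth
  in_thal <- abs(x) > g$thalamus_inner_x & abs(x) <= t[1] &
    abs(y) <= t[2] & abs(z) <= t[3]
  label <- integer(nrow(points))
  label[in_brain] <- LBL_WM
  label[in_brain & in_thal] <- LBL_GM
  label[in_brain & in_vent] <- LBL_CSF
  hc <- g$hab_center; hs <- g$hab_semiaxes
  mR <- ((x - hc[1]) / hs[1])^2 + ((y - hc[2]) / hs[2])^2 +
    ((z - hc[3]) / hs[3])^2
  mL <- ((x + hc[1]) / hs[1])^2 + ((y - hc[2]) / hs[2])^2 +
    ((z - hc[3]) / hs[3])^2
  list(label = label, m_left = mL, m_right = mR)
}

# Pick exactly n voxels per side for the habenula masks, ranked by the
# ellipsoid metric evaluated in template space (deterministic tie-break by
# voxel index). Restricted to brain voxels so the mask cannot leak into
# background on pathological deformations.
select_habenula <- function(geom, n_voxels) {
  ok <- geom$label != LBL_BG
  pick <- function(metric, exclude) {
    cand <- which(ok & metric <= 4 & !exclude)
    if (length(cand) < n_voxels)
      stopf("grid too small to contain structure 'habenula' (%d candidate voxels for %d needed)",
            length(cand), n_voxels)
    cand[order(metric[cand])][seq_len(n_voxels)]
  }
  excl <- rep(FALSE, length(geom$label))
  left <- pick(geom$m_left, excl)
  excl[left] <- TRUE
  right <- pick(geom$m_right, excl)
  list(left = left, right = right)
}
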