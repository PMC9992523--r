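# building phantom subjects (template and sampled individuals)

# Shared constructor: realises a subject from a deformation, per-class
# parameter values, a target per-side habenula volume and field models.
build_truth <- function(spec, deform, class_values, hab_volume_mm3,
                        ft_params, rx_params, subject_index, seed) {
  check_geometry_fits(spec)
  dims <- spec$grid_dims
  voxel <- spec$voxel_size
  voxvol <- voxel^3
  pts <- grid_world(dims, voxel)
  tpl_pts <- deform_forward(deform, pts)   # subject -> template space
  geom <- geom_eval(tpl_pts)

  n_hab <- max(1L, round(hab_volume_mm3 / voxvol))
  sel <- select_habenula(geom, n_hab)
  label <- geom$label
  label[sel$left] <- LBL_HAB
  label[sel$right] <- LBL_HAB

  mk <- function(param) {
    v <- numeric(length(label))
    v[label == LBL_WM] <- class_values$WM[[param]]
    v[label == LBL_GM] <- class_values$GM[[param]]
    v[label == LBL_CSF] <- class_values$CSF[[param]]
    v[label == LBL_HAB] <- class_values$habenula[[param]]
    array(v, dims)
  }
  probs <- lapply(seq_along(TISSUE_CLASSES) - 1L,
                  function(code) array(as.numeric(label == code), dims))
  names(probs) <- TISSUE_CLASSES

  hab_left <- array(FALSE, dims); hab_left[sel$left] <- TRUE
  hab_right <- array(FALSE, dims); hab_right[sel$right] <- TRUE

  g <- hab_geometry()
  pd <- mk("PD")
  subject <- structure(list(
    label = array(label, dims),
    probs = probs,
    R1 = mk("R1"), R2s = mk("R2s"), PD = pd, MTsat = mk("MTsat"),
    A = pd,                       # effective amplitude, arbitrary units = p.u.
    f_T = array(cosfield_eval(ft_params, pts), dims),
    rx = array(cosfield_eval(rx_params, pts), dims),
    ft_params = ft_params, rx_params = rx_params,
    hab_left = hab_left, hab_right = hab_right,
    ac = as.vector(deform_inverse(deform, matrix(g$ac, 1))),
    pc = as.vector(deform_inverse(deform, matrix(g$pc, 1))),
    deformation = deform,
    affine = vox_affine(dims, voxel),
    voxel = voxel, dims = dims,
    class_values = class_values,
    hab_volume_drawn = hab_volume_mm3,
    subject_index = subject_index, seed = seed), class = "subject_truth")
  subject
}

class_means <- function(tissue_params) {
  lapply(tissue_params, function(tp)
    list(R1 = tp$R1_mean, R2s = tp$R2s_mean, PD = tp$PD_mean,
         MTsat = tp$MTsat_mean))
}

#' Build the deterministic template phantom
#'
#' Constructs the cohort template: nested geometry (WM shell, thalamic GM
#' blocks, third-ventricle CSF slab, two ellipsoidal habenulae abutting
#' the ventricle), parameter volumes filled from the per-tissue means
#' without jitter, unit transmit and receive fields, midline AC/PC
#' landmarks, identity deformation. Each habenula mask contains exactly
#' `round(habenula_volume_mean / voxel_volume)` voxels, selected by
#' ellipsoid distance.
#'
#' @param spec a [phantom_spec()].
#' @return a `subject_truth` object: tissue label and probability volumes,
#'   ground-truth R1/R2*/PD/MTsat/A volumes, f_T and receive fields,
#'   habenula masks, AC/PC landmarks, stored deformation and affine.
#' @examples
#' tpl <- build_template(phantom_spec())
#' sum(tpl$hab_left)                      # 38 voxels at 0.8 mm, 19.26 mm^3
#' mean(tpl$R1[tpl$hab_left | tpl$hab_right])
#' @export
build_template <- function(spec) {
  build_truth(spec, deform_identity(), class_means(spec$tissue_params),
              spec$habenula_volume_mean, NULL, NULL,
              subject_index = 0L, seed = NA_integer_)
}

#' @export
print.subject_truth <- function(x, ...) {
  n_hab <- sum(x$hab_left) + sum(x$hab_right)
  cat(sprintf("Phantom subject %s: grid %s @ %g mm\n",
              if (x$subject_index == 0L) "(template)" else x$subject_index,
              paste(x$dims, collapse = "x"), x$voxel))
  cat(sprintf("  brain voxels %d; habenula %d voxels (%.2f mm^3 drawn %.2f)\n",
              sum(x$label != LBL_BG), n_hab, n_hab * x$voxel^3 / 2,
              x$hab_volume_drawn))
  cat(sprintf("  habenula truth: R1 %.3f, R2* %.2f, PD %.2f, MTsat %.3f\n",
              x$class_values$habenula$R1,
              x$class_values$habenula$R2s,
              x$class_values$habenula$PD,
              x$class_values$habenula$MTsat))
  invisible(x)
}

# per-subject parameter draw used by sample_subject (kept separate so the
# sampling distribution can be tested cheaply at large n)
draw_class_values <- function(tissue_params) {
  lapply(tissue_params, function(tp) list(
    R1 = max(1e-3, rnorm(1, tp$R1_mean, tp$R1_sd)),
    R2s = max(1e-3, rnorm(1, tp$R2s_mean, tp$R2s_sd)),
    PD = min(100, max(1e-3, rnorm(1, tp$PD_mean, tp$PD_sd))),
    MTsat = max(0, rnorm(1, tp$MTsat_mean, tp$MTsat_sd))))
}

draw_habenula_volume <- function(spec) {
  max(spec$voxel_size^3, rnorm(1, spec$habenula_volume_mean,
                               spec$habenula_volume_sd))
}

#' Sample one subject of the synthetic cohort
#'
#' Derives a subject-specific phantom from the template geometry by (a) a
#' smooth random invertible deformation (maximum displacement
#' `deformation_amplitude`), (b) per-tissue parameter jitter drawn from
#' the between-subject SDs, (c) a per-side habenula volume drawn from the
#' cohort volume distribution, and (d) smooth multiplicative transmit
#' (f_T in 1 +/- `ft_amplitude`) and receive (1 +/- `rx_amplitude`)
#' fields. Fully reproducible from `(master_seed, subject_index)`.
#'
#' If a drawn deformation fails the invertibility round-trip tolerance
#' (0.1 voxel) it is redrawn (logged); after `max_retries` failures an
#' error is raised.
#'
#' @param template the [build_template()] result (used for validation; the
#'   subject is evaluated from the same analytic geometry).
#' @param spec the [phantom_spec()].
#' @param subject_index integer in `1:cohort_size`.
#' @param max_retries redraw attempts for a non-invertible deformation.
#' @return a `subject_truth` object.
#' @examples
#' spec <- phantom_spec(cohort_size = 2)
#' s1 <- sample_subject(build_template(spec), spec, 1)
#' @export
sample_subject <- function(template, spec, subject_index, max_retries = 5L) {
  if (subject_index < 1 || subject_index > spec$cohort_size)
    stopf("subject_index must be in [1, %d]", spec$cohort_size)
  seed <- subject_seed(spec$master_seed, subject_index)
  set.seed(seed)
  fov <- spec$grid_dims * spec$voxel_size

  deform <- deform_identity()
  if (spec$deformation_amplitude > 0) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      deform <- deform_draw(spec$deformation_amplitude, fov)
      if (deform_invertible(deform, fov, 0.1 * spec$voxel_size)) {
        ok <- TRUE; break
      }
      message(sprintf("subject %d: deformation draw %d failed round-trip, redrawing",
                      subject_index, try))
    }
    if (!ok) stopf("subject %d: no invertible deformation in %d draws",
                   subject_index, max_retries)
  }

  cls <- draw_class_values(spec$tissue_params)
  hab_vol <- draw_habenula_volume(spec)
  ft <- if (spec$ft_amplitude > 0)
    cosfield_draw(runif(1, 0.5, 1) * spec$ft_amplitude, fov) else NULL
  rx <- if (spec$rx_amplitude > 0)
    cosfield_draw(runif(1, 0.5, 1) * spec$rx_amplitude, fov) else NULL

  build_truth(spec, deform, cls, hab_vol, ft, rx, subject_index, seed)
}
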