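# NIfTI + JSON sidecar I/O for phantom subjects and fitted maps

write_vol <- function(arr, path, affine, voxel) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  path
}

read_vol <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  list(data = array(as.numeric(img), dim(img)), affine = unclass(aff)[1:4, 1:4])
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a simulated subject to a BIDS-like directory layout
#'
#' Writes the weighted echo stacks as 4D NIfTI volumes with one JSON
#' sidecar each (keys `FlipAngle` in degrees, `RepetitionTime` and
#' `EchoTimes` in ms, `Weighting`), the B1+ map, the low-resolution
#' receive-calibration pair on its own coarse grid, and the ground truth
#' (parameter volumes, tissue probabilities, habenula masks, landmarks,
#' deformation, realised tissue values) under `truth/`. A
#' `manifest.json` lists every file with its role and MD5 checksum.
#'
#' @param subject a `subject_truth`.
#' @param volumes the matching `echo_volume_set`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_subject <- function(subject, volumes, directory) {
  dir.create(file.path(directory, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  aff <- subject$affine; vx <- subject$voxel
  files <- list()
  add <- function(path, role) files[[length(files) + 1L]] <<-
    list(path = path, role = role)

  for (w in names(volumes$stacks)) {
    f <- file.path(directory, paste0(tolower(w), ".nii.gz"))
    write_vol(volumes$stacks[[w]], f, aff, vx)
    add(f, paste0("echo_stack_", w))
    p <- volumes$protocol[[w]]
    sidecar <- list(Weighting = w, FlipAngle = p$flip_deg,
                    RepetitionTime = p$tr_ms, EchoTimes = p$te_ms,
                    NoiseSigma = volumes$noise_sigma)
    if (w == "MTw") sidecar$MTPulse <- volumes$protocol$mt_pulse
    j <- file.path(directory, paste0(tolower(w), ".json"))
    write_json_file(sidecar, j)
    add(j, paste0("sidecar_", w))
  }

  f <- file.path(directory, "b1map.nii.gz")
  write_vol(volumes$b1, f, aff, vx); add(f, "b1map")
  cal <- volumes$rx_cal
  for (v in c("array_coil", "body_coil")) {
    f <- file.path(directory, paste0("rx_", sub("_coil", "", v), ".nii.gz"))
    write_vol(cal[[v]], f, cal$affine, cal$voxel)
    add(f, paste0("rx_calibration_", v))
  }

  tr <- function(name, arr, role) {
    f <- file.path(directory, "truth", paste0(name, ".nii.gz"))
    write_vol(arr, f, aff, vx); add(f, role)
  }
  tr("r1", subject$R1, "truth_R1")
  tr("r2s", subject$R2s, "truth_R2s")
  tr("pd", subject$PD, "truth_PD")
  tr("mtsat", subject$MTsat, "truth_MTsat")
  tr("amplitude", subject$A, "truth_A")
  tr("ft", subject$f_T, "truth_fT")
  tr("rx", subject$rx, "truth_rx")
  tr("label", subject$label, "truth_label")
  tr("hab_left", subject$hab_left + 0, "mask_habenula_left")
  tr("hab_right", subject$hab_right + 0, "mask_habenula_right")
  for (cls in names(subject$probs))
    tr(paste0("prob_", tolower(cls)), subject$probs[[cls]],
       paste0("tissue_probability_", cls))

  meta <- list(subject_index = subject$subject_index, seed = subject$seed,
               ac = subject$ac, pc = subject$pc,
               voxel = vx, dims = subject$dims,
               hab_volume_drawn = subject$hab_volume_drawn,
               class_values = subject$class_values,
               deformation = deform_to_list(subject$deformation),
               ft_params = subject$ft_params, rx_params = subject$rx_params)
  f <- file.path(directory, "truth", "subject.json")
  write_json_file(meta, f); add(f, "truth_metadata")

  manifest <- lapply(files, function(fl)
    list(path = sub(paste0("^", directory, "/?"), "", fl$path),
         role = fl$role,
         md5 = unname(tools::md5sum(fl$path))))
  write_json_file(manifest, file.path(directory, "manifest.json"))
  invisible(manifest)
}

#' Read a subject directory written by [write_subject()]
#'
#' @param directory subject directory.
#' @return a list with `stacks`, `protocol` (reconstructed from sidecars),
#'   `b1`, `rx_cal`, `truth` (a `subject_truth`), `affine`, `voxel`.
#' @export
read_subject <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path))
    stopf("no manifest.json in '%s'", directory)
  meta <- read_json_file(file.path(directory, "truth", "subject.json"))
  dims <- as.integer(meta$dims); vx <- meta$voxel
  aff <- vox_affine(dims, vx)

  stacks <- list(); proto <- list()
  for (w in c("T1w", "PDw", "MTw")) {
    f <- file.path(directory, paste0(tolower(w), ".nii.gz"))
    if (!file.exists(f)) next
    stacks[[w]] <- read_vol(f)$data
    sc <- read_json_file(file.path(directory, paste0(tolower(w), ".json")))
    proto[[w]] <- list(flip_deg = sc$FlipAngle, tr_ms = sc$RepetitionTime,
                       te_ms = as.numeric(sc$EchoTimes))
    if (!is.null(sc$MTPulse)) proto$mt_pulse <- sc$MTPulse
  }
  class(proto) <- "mpm_protocol"

  rd <- function(name) read_vol(file.path(directory, "truth",
                                          paste0(name, ".nii.gz")))$data
  probs <- lapply(TISSUE_CLASSES, function(cls) rd(paste0("prob_", tolower(cls))))
  names(probs) <- TISSUE_CLASSES
  # class_values arrive as nested lists from JSON; coerce to numeric lists
  cls_vals <- lapply(meta$class_values, function(cv) lapply(cv, as.numeric))
  truth <- structure(list(
    label = array(as.integer(rd("label")), dims), probs = probs,
    R1 = rd("r1"), R2s = rd("r2s"), PD = rd("pd"), MTsat = rd("mtsat"),
    A = rd("amplitude"), f_T = rd("ft"), rx = rd("rx"),
    ft_params = meta$ft_params, rx_params = meta$rx_params,
    hab_left = rd("hab_left") > 0.5, hab_right = rd("hab_right") > 0.5,
    ac = as.numeric(meta$ac), pc = as.numeric(meta$pc),
    deformation = deform_from_list(meta$deformation),
    affine = aff, voxel = vx, dims = dims,
    class_values = cls_vals,
    hab_volume_drawn = meta$hab_volume_drawn,
    subject_index = meta$subject_index, seed = meta$seed),
    class = "subject_truth")

  b1 <- read_vol(file.path(directory, "b1map.nii.gz"))$data
  rx_a <- read_vol(file.path(directory, "rx_array.nii.gz"))
  rx_b <- read_vol(file.path(directory, "rx_body.nii.gz"))
  cal_dims <- dim(rx_a$data)
  sidecar <- read_json_file(file.path(directory, "pdw.json"))
  list(stacks = stacks, protocol = proto, b1 = b1,
       rx_cal = list(array_coil = rx_a$data, body_coil = rx_b$data,
                     affine = rx_a$affine, dims = cal_dims,
                     voxel = rx_a$affine[1, 1]),
       truth = truth, affine = aff, voxel = vx, dims = dims,
       noise_sigma = sidecar$NoiseSigma %||% 0)
}
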