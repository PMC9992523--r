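# run configuration, full-pipeline orchestration and reporting

#' Pipeline run configuration
#'
#' Bundles the phantom spec, the acquisition protocol and every analysis
#' option into one object that round-trips losslessly through YAML
#' ([write_config()] / [read_config()]), so a full run is reproducible
#' from the config file and the master seed alone.
#'
#' @param spec a [phantom_spec()].
#' @param protocol an [mpm_protocol()].
#' @param gm_threshold GM probability threshold for surround masks.
#' @param connectivity dilation connectivity (6 or 26).
#' @param pd_wm WM calibration value for PD (p.u.).
#' @param b1_correction use the B1+ map during fitting.
#' @param thresholds probability-threshold grid for the sweep.
#' @param smoothing_fwhm template-space smoothing FWHM in mm.
#' @param acpc_roundtrip run native ROI statistics on masks that have
#'   made the AC-PC reorientation round-trip (emulating the manual
#'   delineation workflow) instead of the ground-truth masks directly.
#' @param brain_rule brain-mask rule for normalised volume ("sum" or
#'   "per_class").
#' @param sd_type ROI standard-deviation convention.
#' @return a `habmpm_config` object.
#' @export
habmpm_config <- function(spec = phantom_spec(),
                          protocol = mpm_protocol(),
                          gm_threshold = 0.9,
                          connectivity = 6L,
                          pd_wm = 69,
                          b1_correction = TRUE,
                          thresholds = seq(0.05, 0.95, by = 0.05),
                          smoothing_fwhm = 0.8,
                          acpc_roundtrip = FALSE,
                          brain_rule = "sum",
                          sd_type = "population") {
  structure(list(spec = spec, protocol = protocol,
                 gm_threshold = gm_threshold,
                 connectivity = as.integer(connectivity),
                 pd_wm = pd_wm, b1_correction = b1_correction,
                 thresholds = thresholds,
                 smoothing_fwhm = smoothing_fwhm,
                 acpc_roundtrip = acpc_roundtrip,
                 brain_rule = brain_rule, sd_type = sd_type),
            class = "habmpm_config")
}

#' Write / read a run configuration as YAML
#' @param config a [habmpm_config()].
#' @param path file path.
#' @return `write_config` returns `path`; `read_config` the config.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  x$spec$tissue_params <- lapply(x$spec$tissue_params, unclass)
  x$protocol <- unclass(x$protocol)
  writeLines(yaml::as.yaml(x, precision = 12), path)
  path
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  tp <- lapply(x$spec$tissue_params, function(t) do.call(tissue_params, t))
  spec_args <- x$spec
  spec_args$tissue_params <- tp
  spec <- do.call(phantom_spec, spec_args)
  proto <- x$protocol
  class(proto) <- "mpm_protocol"
  validate_protocol(proto)
  cfg_args <- x[setdiff(names(x), c("spec", "protocol"))]
  do.call(habmpm_config, c(list(spec = spec, protocol = proto), cfg_args))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

na_to_zero <- function(arr) { arr[!is.finite(arr)] <- 0; arr }

stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed for subject %s: %s", name,
          as.character(subject), conditionMessage(e)))
}

#' Run the complete pipeline on a synthetic cohort
#'
#' Simulates the cohort (template, per-subject phantoms, FLASH forward
#' model, noise), writes each subject to disk, estimates quantitative
#' maps, runs the native-space ROI/volumetry/CNR analysis and the
#' group-space atlas and threshold-sweep analysis, and writes tabular
#' reports (`native_stats.csv`, `cnr.csv`, `sweep.csv`), template-space
#' volumes, and a run manifest with the config hash and per-file
#' checksums. Fully reproducible from (config, master seed).
#'
#' @param config a [habmpm_config()].
#' @param out_dir output directory.
#' @param verbose print per-stage progress.
#' @return a `cohort_report`: per-subject tables, cohort summaries,
#'   atlas, averages, sweep, config and output paths.
#' @export
run_all <- function(config = habmpm_config(),
                    out_dir = tempfile("habmpm_run"), verbose = TRUE) {
  spec <- config$spec
  proto <- config$protocol
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  template <- stage("template", 0, build_template(spec))
  native_rows <- list(); cnr_entries <- list()
  warped_maps <- list(); hab_weights <- list(); gm_warp <- list()

  for (i in seq_len(spec$cohort_size)) {
    ti <- Sys.time()
    subj <- stage("sample_subject", i, sample_subject(template, spec, i))
    vols <- stage("simulate_flash", i, simulate_flash(subj, proto, spec))
    vols <- stage("add_noise", i,
                  add_noise(vols, spec, subject_seed(spec$master_seed, i, 1L)))
    sdir <- file.path(out_dir, "subjects", sprintf("sub-%02d", i))
    stage("write_subject", i, write_subject(subj, vols, sdir))
    maps <- stage("fit_maps", i,
                  run_mpm(sdir, out_dir = file.path(sdir, "maps"),
                          b1_correction = config$b1_correction,
                          pd_wm = config$pd_wm))

    hab <- subj$hab_left | subj$hab_right
    hab_l <- subj$hab_left; hab_r <- subj$hab_right
    if (config$acpc_roundtrip) {
      hab_l <- acpc_roundtrip_mask(hab_l, subj$ac, subj$pc, subj$affine)
      hab_r <- acpc_roundtrip_mask(hab_r, subj$ac, subj$pc, subj$affine)
      hab <- hab_l | hab_r
    }
    vol_row <- stage("volumetry", i,
                     habenula_volumes(hab_l, hab_r, subj$probs,
                                      spec$voxel_size,
                                      brain_rule = config$brain_rule))
    map_list <- list(R1 = maps$R1, R2s = maps$R2s, PD = maps$PD,
                     MTsat = maps$MTsat)
    for (m in names(map_list)) {
      if (is.null(map_list[[m]])) next
      st <- stage("roi_stats", i,
                  roi_stats(map_list[[m]], hab, spec$voxel_size,
                            map_name = m, sd_type = config$sd_type))
      native_rows[[length(native_rows) + 1L]] <-
        cbind(data.frame(subject = i), st, vol_row)
    }
    cnr_entries[[i]] <- list(subject = i, maps = map_list, hab_mask = hab,
                             gm_prob = subj$probs$GM)

    w <- stage("warp_to_template", i,
               warp_to_template(subj, lapply(map_list, na_to_zero),
                                misalignment_sd = spec$misalignment_sd,
                                smoothing_fwhm = config$smoothing_fwhm,
                                seed = subject_seed(spec$master_seed, i, 2L),
                                gm_prob = subj$probs$GM))
    warped_maps[[i]] <- w$maps
    hab_weights[[i]] <- w$hab_weight
    gm_warp[[i]] <- w$gm
    say("subject %02d done (%.1f s)", i,
        as.numeric(difftime(Sys.time(), ti, units = "secs")))
  }

  cnr <- stage("native_cnr", "cohort",
               native_cnr_report(cnr_entries, config$gm_threshold,
                                 config$connectivity))
  native <- do.call(rbind, native_rows)

  map_names <- names(Filter(Negate(is.null), warped_maps[[1]]))
  avg_maps <- lapply(setNames(map_names, map_names), function(m)
    average_maps(lapply(warped_maps, `[[`, m)))
  atlas <- stage("atlas", "cohort", probability_map(hab_weights))
  gm_avg <- average_maps(gm_warp)
  gm_roi <- stage("fixed_gm_roi", "cohort",
                  fixed_gm_roi(atlas, gm_avg, config$gm_threshold,
                               config$connectivity))
  sweep <- stage("threshold_sweep", "cohort",
                 threshold_sweep(avg_maps, atlas, gm_roi,
                                 config$thresholds, spec$voxel_size))

  report <- structure(list(native = native, cnr = cnr, sweep = sweep,
                           atlas = atlas, avg_maps = avg_maps,
                           gm_avg = gm_avg, gm_roi = gm_roi,
                           config = config, out_dir = out_dir,
                           runtime_s = as.numeric(
                             difftime(Sys.time(), t0, units = "secs"))),
                      class = "cohort_report")

  # tabular outputs (byte-stable: plain write.csv, fixed column order)
  write.csv(native, file.path(out_dir, "native_stats.csv"),
            row.names = FALSE)
  cnr_plain <- cnr; attributes(cnr_plain)[c("summary", "ranking")] <- NULL
  write.csv(cnr_plain, file.path(out_dir, "cnr.csv"), row.names = FALSE)
  write.csv(as.data.frame(unclass(sweep)), file.path(out_dir, "sweep.csv"),
            row.names = FALSE)
  tpl_aff <- template$affine
  write_vol(unclass(atlas), file.path(out_dir, "habenula_probability.nii.gz"),
            tpl_aff, spec$voxel_size)
  for (m in map_names)
    write_vol(avg_maps[[m]], file.path(out_dir, paste0("avg_", m, ".nii.gz")),
              tpl_aff, spec$voxel_size)
  write_config(config, file.path(out_dir, "config.yaml"))

  summ <- summarize_report(report)
  write_json_file(summ, file.path(out_dir, "summary.json"))
  writeLines(format_summary(summ), file.path(out_dir, "summary.txt"))

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(config_hash = config_hash(config),
                   master_seed = spec$master_seed,
                   files = lapply(out_files, function(f)
                     list(path = sub(paste0("^", out_dir, "/?"), "", f),
                          md5 = unname(tools::md5sum(f)))))
  write_json_file(manifest, file.path(out_dir, "run_manifest.json"))
  report
}

cohort_map_summary <- function(native) {
  maps <- unique(native$map)
  do.call(rbind, lapply(maps, function(m) {
    v <- native$mean[native$map == m]
    data.frame(map = m, cohort_mean = mean(v),
               cohort_sd = if (length(v) > 1) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
}

#' Summarise a cohort report
#'
#' One-page summary of a [run_all()] report: cohort-mean map values in
#' the habenula, volumetry, the CNR ranking across maps, the atlas
#' maximum probability, and per map the first sweep threshold at which
#' the group-space CNR magnitude exceeds the native cohort-mean CNR
#' magnitude (`NA` when it never does). Cohort means are recomputed from
#' the per-subject rows on the fly, so the summary is always consistent
#' with the tables.
#'
#' @param report a `cohort_report` from [run_all()].
#' @return a named list (serialised to `summary.json` by [run_all()];
#'   [format_summary()] renders the identical numbers as text).
#' @export
summarize_report <- function(report) {
  need <- c("native", "cnr", "sweep", "atlas")
  missing <- need[!vapply(need, function(n) !is.null(report[[n]]), TRUE)]
  if (length(missing))
    stopf("incomplete report: missing %s", paste(missing, collapse = ", "))
  native <- report$native
  maps_summ <- cohort_map_summary(native)
  one_per_subj <- native[!duplicated(native$subject), ]
  vols <- list(
    left_mean = mean(one_per_subj$vol_left_mm3),
    left_sd = sd0(one_per_subj$vol_left_mm3),
    right_mean = mean(one_per_subj$vol_right_mm3),
    right_sd = sd0(one_per_subj$vol_right_mm3),
    mean_mean = mean(one_per_subj$vol_mean_mm3),
    mean_sd = sd0(one_per_subj$vol_mean_mm3),
    norm_pct_mean = mean(one_per_subj$vol_norm_pct),
    norm_pct_sd = sd0(one_per_subj$vol_norm_pct))
  cnr_summ <- attr(report$cnr, "summary")
  ranking <- as.character(attr(report$cnr, "ranking"))

  crossing <- list()
  for (m in cnr_summ$map) {
    native_cnr <- cnr_summ$cnr_mean[cnr_summ$map == m]
    col <- paste0("cnr_", m)
    if (!col %in% names(report$sweep)) next
    hit <- which(abs(report$sweep[[col]]) > abs(native_cnr))
    crossing[[m]] <- if (length(hit)) report$sweep$threshold[min(hit)]
    else NA_real_
  }

  list(maps = maps_summ, volumes = vols,
       cnr = cnr_summ, cnr_ranking = ranking,
       atlas = list(maximum = attr(report$atlas, "maximum"),
                    n_at_maximum = attr(report$atlas, "n_at_maximum"),
                    n_subjects = attr(report$atlas, "n_subjects")),
       sweep_crossing_threshold = crossing,
       n_subjects = length(unique(native$subject)))
}

sd0 <- function(x) if (length(x) > 1) sd(x) else 0

#' Render a summary as text
#' @param summ a [summarize_report()] result.
#' @return character vector of lines containing the same numbers as the
#'   JSON summary (rounded identically for display).
#' @export
format_summary <- function(summ) {
  num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)
  lines <- c(sprintf("Cohort summary (%d subjects)", summ$n_subjects),
             "Habenula ROI cohort means:")
  for (i in seq_len(nrow(summ$maps)))
    lines <- c(lines, sprintf("  %-5s %s +/- %s", summ$maps$map[i],
                              num(summ$maps$cohort_mean[i]),
                              num(summ$maps$cohort_sd[i])))
  v <- summ$volumes
  lines <- c(lines,
             sprintf("Volumes (mm^3): left %s +/- %s, right %s +/- %s, mean %s +/- %s",
                     num(v$left_mean), num(v$left_sd), num(v$right_mean),
                     num(v$right_sd), num(v$mean_mean), num(v$mean_sd)),
             sprintf("Normalised volume: %s +/- %s %%",
                     num(v$norm_pct_mean), num(v$norm_pct_sd)),
             sprintf("CNR ranking: %s", paste(summ$cnr_ranking, collapse = " > ")))
  for (i in seq_len(nrow(summ$cnr)))
    lines <- c(lines, sprintf("  CNR %-5s %s +/- %s", summ$cnr$map[i],
                              num(summ$cnr$cnr_mean[i]),
                              num(summ$cnr$cnr_sd[i])))
  lines <- c(lines,
             sprintf("Atlas maximum probability: %s at %d voxel(s) of %d subjects",
                     num(summ$atlas$maximum), summ$atlas$n_at_maximum,
                     summ$atlas$n_subjects),
             "Sweep threshold where group CNR first exceeds native CNR:")
  for (m in names(summ$sweep_crossing_threshold)) {
    x <- summ$sweep_crossing_threshold[[m]]
    lines <- c(lines, sprintf("  %-5s %s", m,
                              if (is.na(x)) "undefined" else num(x)))
  }
  lines
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format_summary(summarize_report(x)), sep = "\n")
  cat(sprintf("Outputs in %s (%.1f s)\n", x$out_dir, x$runtime_s))
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) summarize_report(object)
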