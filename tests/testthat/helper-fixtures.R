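# shared fixtures, built in code

default_spec <- function(...) phantom_spec(...)

# spec with every stochastic component switched off: sampled subjects
# must equal the template
frozen_spec <- function(...) {
  sp <- phantom_spec(deformation_amplitude = 0, habenula_volume_sd = 0,
                     ft_amplitude = 0, rx_amplitude = 0, noise_sigma = 0,
                     ...)
  sp$tissue_params <- lapply(sp$tissue_params, function(tp) {
    tp$R1_sd <- 0; tp$R2s_sd <- 0; tp$PD_sd <- 0; tp$MTsat_sd <- 0
    tp
  })
  sp
}

# independent steady-state oracle: iterate the per-TR longitudinal
# recursion (saturation -> excitation -> relaxation) to convergence
flash_steady_state_oracle <- function(A, R1, tr_s, alpha, d = 0,
                                      c_rx = 1, n_iter = 5000) {
  E1 <- exp(-tr_s * R1)
  mz <- 1
  for (i in seq_len(n_iter))
    mz <- 1 - E1 + mz * (1 - d) * cos(alpha) * E1
  c_rx * A * sin(alpha) * (1 - d) * mz
}

# one simulated, written and fitted subject, cached across tests in a file
fitted_subject_fixture <- local({
  cache <- new.env()
  function(noise = FALSE) {
    key <- if (noise) "noisy" else "clean"
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- phantom_spec(noise_sigma = if (noise) NULL else 0)
    tpl <- build_template(spec)
    s <- sample_subject(tpl, spec, 1)
    vols <- simulate_flash(s, mpm_protocol(), spec)
    if (noise) vols <- add_noise(vols, spec, seed = 11L)
    dir <- file.path(tempdir(), paste0("habmpm_fix_", key))
    if (!file.exists(file.path(dir, "manifest.json")))
      write_subject(s, vols, dir)
    maps <- suppressMessages(run_mpm(dir))
    cache[[key]] <- list(spec = spec, template = tpl, subject = s,
                         volumes = vols, dir = dir, maps = maps)
    cache[[key]]
  }
})
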