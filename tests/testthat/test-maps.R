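# rational-approximation estimators against the exact forward model

intercepts_for <- function(R1, f_T = 1, A = 100, proto = mpm_protocol()) {
  tr <- proto$T1w$tr_ms / 1000
  list(S_T1 = habmpm:::flash_signal(A, R1, 0, tr,
                                    f_T * proto$T1w$flip_deg * pi / 180),
       S_PD = habmpm:::flash_signal(A, R1, 0, tr,
                                    f_T * proto$PDw$flip_deg * pi / 180))
}

test_that("R1 and amplitude recover truth within the documented bias bounds", {
  proto <- mpm_protocol()
  for (R1 in seq(0.5, 1.5, by = 0.25)) {
    for (f_T in c(0.9, 1.0, 1.1)) {
      s <- intercepts_for(R1, f_T)
      r1_hat <- compute_r1(s$S_T1, s$S_PD, proto, f_T)
      expect_lt(abs(r1_hat / R1 - 1), 0.02,
                label = sprintf("R1 bias at R1=%g fT=%g", R1, f_T))
      a_hat <- compute_amplitude(s$S_T1, s$S_PD, proto, f_T)
      expect_lt(abs(a_hat / 100 - 1), 0.02,
                label = sprintf("A bias at R1=%g fT=%g", R1, f_T))
    }
  }
})

test_that("B1 correction makes recovery transmit-independent", {
  proto <- mpm_protocol()
  s1 <- intercepts_for(0.86, 1.0)
  s2 <- intercepts_for(0.86, 0.9)
  r_nominal <- compute_r1(s1$S_T1, s1$S_PD, proto, 1.0)
  r_corrected <- compute_r1(s2$S_T1, s2$S_PD, proto, 0.9)
  expect_equal(as.numeric(r_corrected), as.numeric(r_nominal),
               tolerance = 0.005)
})

test_that("amplitude estimator is homogeneous and flip-symmetric", {
  proto <- mpm_protocol()
  s <- intercepts_for(0.9)
  a1 <- compute_amplitude(s$S_T1, s$S_PD, proto)
  a2 <- compute_amplitude(3.7 * s$S_T1, 3.7 * s$S_PD, proto)
  expect_equal(as.numeric(a2), 3.7 * as.numeric(a1), tolerance = 1e-12)
  r1a <- compute_r1(s$S_T1, s$S_PD, proto)
  r1b <- compute_r1(3.7 * s$S_T1, 3.7 * s$S_PD, proto)
  expect_equal(as.numeric(r1a), as.numeric(r1b), tolerance = 1e-12)

  # swapping the two inputs together with their flip angles is a no-op
  proto_sw <- proto
  proto_sw$T1w$flip_deg <- proto$PDw$flip_deg
  proto_sw$PDw$flip_deg <- proto$T1w$flip_deg
  a3 <- compute_amplitude(s$S_PD, s$S_T1, proto_sw)
  expect_equal(as.numeric(a3), as.numeric(a1), tolerance = 1e-12)
})

test_that("degenerate intercept pairs are masked, not propagated", {
  proto <- mpm_protocol()
  a_t1 <- proto$T1w$flip_deg * pi / 180
  a_pd <- proto$PDw$flip_deg * pi / 180
  S_T1 <- 50
  S_PD <- S_T1 * a_pd / a_t1   # S_PD/a_PD == S_T1/a_T1
  r1 <- compute_r1(S_T1, S_PD, proto)
  expect_true(is.na(as.numeric(r1)))
  expect_identical(attr(r1, "n_masked"), 1L)
})

test_that("PD calibration removes the receive field and any global scale", {
  dims <- c(12L, 12L, 12L)
  vx <- 0.8
  aff <- habmpm:::vox_affine(dims, vx)
  pd_true <- array(76.21, dims)
  wm <- array(FALSE, dims); wm[1:6, , ] <- TRUE
  pd_true[wm] <- 69
  cal_dims <- c(4L, 4L, 4L)
  rx_cal <- list(array_coil = array(5.5, cal_dims),
                 body_coil = array(1, cal_dims),
                 affine = habmpm:::vox_affine(cal_dims, 8), voxel = 8)
  for (c_global in c(0.4, 1, 3)) {
    pd <- compute_pd(pd_true * c_global, rx_cal, wm, aff, vx)
    expect_equal(as.vector(pd), as.vector(pd_true), tolerance = 1e-9)
  }
  # doubling the receive field everywhere changes nothing
  rx2 <- rx_cal; rx2$array_coil <- rx_cal$array_coil * 2
  expect_equal(as.vector(compute_pd(pd_true, rx2, wm, aff, vx)),
               as.vector(compute_pd(pd_true, rx_cal, wm, aff, vx)),
               tolerance = 1e-9)
  expect_error(compute_pd(pd_true, rx_cal, array(FALSE, dims), aff, vx),
               "WM mask")
})

test_that("MTsat recovers the saturation with small, bounded bias", {
  proto <- mpm_protocol()
  tr <- proto$MTw$tr_ms / 1000
  a_mt <- proto$MTw$flip_deg * pi / 180
  for (delta in c(0, 0.005, 0.0105, 0.02)) {
    s <- intercepts_for(0.86)
    S_MT <- habmpm:::flash_signal(100, 0.86, 0, tr, a_mt, d = delta)
    R1 <- compute_r1(s$S_T1, s$S_PD, proto, 1)
    A <- compute_amplitude(s$S_T1, s$S_PD, proto, 1)
    mts <- compute_mtsat(S_MT, A, R1, proto, 1)
    if (delta == 0) {
      expect_lt(abs(as.numeric(mts)), 0.02)  # p.u.
    } else {
      expect_lt(abs(as.numeric(mts) / (100 * delta) - 1), 0.03)
    }
  }
  # at nominal transmit the bias correction is exactly neutral
  s <- intercepts_for(0.86)
  S_MT <- habmpm:::flash_signal(100, 0.86, 0, tr, a_mt, d = 0.0105)
  R1 <- compute_r1(s$S_T1, s$S_PD, proto, 1)
  A <- compute_amplitude(s$S_T1, s$S_PD, proto, 1)
  expect_identical(as.numeric(compute_mtsat(S_MT, A, R1, proto, 1)),
                   as.numeric(compute_mtsat(S_MT, A, R1, proto, 1,
                                            b1_correction = FALSE)))
  # out-of-range results are masked
  bad <- compute_mtsat(-1, 100, 0.86, proto, 1)
  expect_true(is.na(as.numeric(bad)))
})

test_that("the full noise-free chain recovers habenula truth", {
  fx <- fitted_subject_fixture(noise = FALSE)
  s <- fx$subject; maps <- fx$maps
  hab <- s$hab_left | s$hab_right
  cv <- s$class_values$habenula
  expect_lt(abs(mean(maps$R1[hab]) / cv$R1 - 1), 0.02)
  expect_lt(abs(mean(maps$R2s[hab]) / cv$R2s - 1), 0.01)
  expect_lt(abs(mean(maps$PD[hab]) / cv$PD - 1), 0.03)
  expect_lt(abs(mean(maps$MTsat[hab]) / cv$MTsat - 1), 0.03)

  # rerun on the same inputs is bit-identical
  again <- suppressMessages(run_mpm(fx$dir))
  expect_identical(again$R1, maps$R1)
  expect_identical(again$PD, maps$PD)
})

test_that("a missing MTw stack degrades gracefully", {
  fx <- fitted_subject_fixture(noise = FALSE)
  dir2 <- file.path(tempdir(), "habmpm_nomt")
  unlink(dir2, recursive = TRUE)
  fs <- list.files(fx$dir, recursive = TRUE)
  for (f in fs) {
    dir.create(dirname(file.path(dir2, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(fx$dir, f), file.path(dir2, f))
  }
  unlink(file.path(dir2, c("mtw.nii.gz", "mtw.json")))
  expect_warning(maps <- run_mpm(dir2), "MTw stack absent")
  expect_null(maps$MTsat)
  expect_false(is.null(maps$R1))
  expect_equal(maps$R1, fx$maps$R1, tolerance = 1e-6)
  unlink(dir2, recursive = TRUE)
})

test_that("moderate noise barely moves the ROI means", {
  # SNR 50: ROI means within 1% of the noise-free fit
  clean <- fitted_subject_fixture(noise = FALSE)
  spec50 <- phantom_spec(target_snr = 50)
  vols <- add_noise(clean$volumes, spec50, seed = 21L)
  dir50 <- file.path(tempdir(), "habmpm_snr50")
  unlink(dir50, recursive = TRUE)
  write_subject(clean$subject, vols, dir50)
  noisy <- suppressMessages(run_mpm(dir50))
  hab <- clean$subject$hab_left | clean$subject$hab_right
  for (m in c("R1", "R2s", "PD", "MTsat")) {
    expect_lt(abs(mean(noisy[[m]][hab], na.rm = TRUE) /
                    mean(clean$maps[[m]][hab]) - 1), 0.01, label = m)
  }
  unlink(dir50, recursive = TRUE)
})
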