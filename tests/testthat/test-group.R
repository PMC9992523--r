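test_that("identity warp with no perturbation or smoothing is bit-exact", {
  spec <- frozen_spec()
  tpl <- build_template(spec)
  w <- warp_to_template(tpl, list(R1 = tpl$R1), misalignment_sd = 0,
                        smoothing_fwhm = 0, seed = 1L,
                        gm_prob = tpl$probs$GM)
  expect_identical(w$maps$R1, tpl$R1)
  expect_identical(w$hab_weight, (tpl$hab_left | tpl$hab_right) + 0)
  expect_identical(w$gm, tpl$probs$GM)
})

test_that("warped mask weights stay within [0, 1] under any settings", {
  spec <- phantom_spec()
  tpl <- build_template(spec)
  s <- sample_subject(tpl, spec, 3)
  for (cfg in list(c(0, 0.8), c(0.4, 0.8), c(1.0, 2.0))) {
    w <- warp_to_template(s, list(), misalignment_sd = cfg[1],
                          smoothing_fwhm = cfg[2], seed = 5L)
    expect_gte(min(w$hab_weight), 0)
    expect_lte(max(w$hab_weight), 1)
  }
  # seeded: same seed, same perturbation
  w1 <- warp_to_template(s, list(), 0.4, 0.8, seed = 9L)
  w2 <- warp_to_template(s, list(), 0.4, 0.8, seed = 9L)
  expect_identical(w1$hab_weight, w2$hab_weight)
  expect_identical(w1$shift, w2$shift)
})

test_that("the probability atlas counts subject coverage", {
  d <- c(8L, 8L, 8L)
  base <- array(0, d); base[4:5, 4:5, 4] <- 1
  # 26 identical masks: maximum 1
  atlas <- probability_map(rep(list(base), 26))
  expect_equal(attr(atlas, "maximum"), 1)
  # a voxel present in 22 of 26 masks
  masks <- rep(list(base), 26)
  off <- array(0, d); off[4, 4, 4] <- 1   # only one voxel
  masks[23:26] <- list(off, off, off, off)
  atlas <- probability_map(masks)
  expect_equal(atlas[5, 5, 4], 22 / 26)
  expect_equal(atlas[4, 4, 4], 1)
  # single subject: atlas equals its mask
  expect_equal(unclass(probability_map(list(base)))[, , ], base[, , ],
               ignore_attr = TRUE)
})

test_that("average_maps is the voxelwise mean on a common grid", {
  d <- c(4L, 4L, 4L)
  a <- array(1, d); b <- array(3, d)
  expect_equal(average_maps(list(a, b)), array(2, d))
  expect_equal(average_maps(list(a, a, a)), a)
  expect_error(average_maps(list(a, array(1, c(5L, 4L, 4L)))),
               "grid mismatch")
})

test_that("cohort averaging reduces within-ROI noise", {
  spec <- phantom_spec()
  tpl <- build_template(spec)
  hab <- tpl$hab_left | tpl$hab_right
  set.seed(55)
  noisy <- lapply(1:8, function(i) tpl$R1 + array(rnorm(length(tpl$R1),
                                                        0, 0.05),
                                                  dim(tpl$R1)))
  avg <- average_maps(noisy)
  sd_single <- sd(noisy[[1]][hab])
  sd_avg <- sd(avg[hab])
  expect_lt(sd_avg, sd_single)
})

test_that("the fixed GM ROI is the ring around the atlas support", {
  d <- c(9L, 9L, 9L)
  a <- array(0, d); a[5, 5, 5] <- 0.7
  atlas <- probability_map(list(a))
  gm <- array(1, d)
  roi <- fixed_gm_roi(atlas, gm)
  expect_identical(sum(roi), 6L)
  expect_false(any(roi & (unclass(atlas) > 0)))
  expect_error(fixed_gm_roi(atlas, gm, threshold = 1.1), "empty")
})

test_that("the threshold sweep has monotone volume and honest missings", {
  d <- c(9L, 9L, 9L)
  a <- array(0, d)
  a[4:6, 4:6, 4:6] <- 0.3; a[5, 5, 4:6] <- 0.6; a[5, 5, 5] <- 0.9
  atlas <- probability_map(list(a))
  gm_roi <- fixed_gm_roi(atlas, array(1, d))
  avg <- list(R1 = array(0.7, d) + a * 0.3)
  sw <- threshold_sweep(avg, atlas, gm_roi, voxel_size = 0.8)
  expect_true(all(diff(sw$roi_vol_mm3) <= 0))
  expect_true(all(is.na(sw$cnr_R1[sw$threshold > 0.9])))
  expect_error(threshold_sweep(avg, atlas, gm_roi, thresholds = c(0.5, 0.2)),
               "strictly increasing")

  # single subject, no misalignment, no smoothing: any threshold in (0,1)
  # below the mask value selects exactly the subject mask
  spec <- frozen_spec()
  tpl <- build_template(spec)
  w <- warp_to_template(tpl, list(R1 = tpl$R1), 0, 0, seed = 1L)
  atlas1 <- probability_map(list(w$hab_weight))
  mask_n <- sum(tpl$hab_left | tpl$hab_right)
  sw1 <- threshold_sweep(list(R1 = w$maps$R1), atlas1,
                         fixed_gm_roi(atlas1, tpl$probs$GM),
                         thresholds = c(0.2, 0.5, 0.8),
                         voxel_size = spec$voxel_size)
  expect_true(all(sw1$roi_vol_mm3 == mask_n * spec$voxel_size^3))
})

test_that("atlas mass is conserved through warping and smoothing", {
  spec <- phantom_spec(cohort_size = 4)
  tpl <- build_template(spec)
  weights <- list(); vols <- numeric(0)
  for (i in 1:4) {
    s <- sample_subject(tpl, spec, i)
    w <- warp_to_template(s, list(), misalignment_sd = 0.4,
                          smoothing_fwhm = 0.8,
                          seed = habmpm:::subject_seed(1, i, 2L))
    weights[[i]] <- w$hab_weight
    vols[i] <- sum(s$hab_left | s$hab_right) * spec$voxel_size^3
  }
  atlas <- probability_map(weights)
  atlas_vol <- sum(atlas) * spec$voxel_size^3
  expect_lt(abs(atlas_vol / mean(vols) - 1), 0.05)

  # residual misalignment prevents perfect overlap
  expect_lt(attr(atlas, "maximum"), 1)
  expect_gt(attr(atlas, "maximum"), 0.2)
})
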