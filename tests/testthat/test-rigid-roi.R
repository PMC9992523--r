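random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, rnorm(3, sd = 5))
}

test_that("rigid transforms satisfy the group axioms", {
  set.seed(31)
  pts <- matrix(rnorm(60, sd = 10), 20)
  for (i in 1:10) {
    a <- random_rigid(); b <- random_rigid()
    # inverse contract
    expect_lt(max(abs(apply_rigid(compose_rigid(invert_rigid(a), a), pts) -
                        pts)), 1e-10)
    # associativity against point-wise application
    expect_lt(max(abs(apply_rigid(compose_rigid(a, b), pts) -
                        apply_rigid(a, apply_rigid(b, pts)))), 1e-10)
  }
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("AC-PC alignment maps the landmarks onto the -y axis", {
  # already aligned: identity
  tf <- acpc_transform(c(0, 5, 0), c(0, -5, 0))
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-12)

  set.seed(32)
  for (i in 1:10) {
    ac <- rnorm(3, sd = 10); pc <- rnorm(3, sd = 10)
    tf <- acpc_transform(ac, pc)
    out <- apply_rigid(tf, rbind(ac, pc))
    # symmetric about the origin, on the y axis
    expect_lt(max(abs(out[1, ] + out[2, ])), 1e-9)
    expect_lt(max(abs(out[, c(1, 3)])), 1e-9)
    expect_lt(out[2, 2], 0)  # PC ends up at negative y
    # round-trip on a point cloud
    cloud <- matrix(rnorm(300, sd = 20), 100)
    back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, cloud))
    expect_lt(max(abs(back - cloud)), 1e-9)
  }
  expect_error(acpc_transform(c(1, 2, 3), c(1, 2, 3)), "coincide")
})

test_that("resampling under identity and unit translations is exact", {
  spec <- phantom_spec()
  tpl <- build_template(spec)
  vol <- tpl$R1
  idt <- rigid_transform()
  expect_identical(resample(vol, idt, tpl$affine), vol)
  expect_identical(resample(vol, idt, tpl$affine, "nearest"), vol)

  # one-voxel translation shifts indices exactly
  tr <- rigid_transform(translation = c(spec$voxel_size, 0, 0))
  shifted <- resample(vol, tr, tpl$affine, "nearest")
  expect_equal(shifted[2:48, , ], vol[1:47, , ], tolerance = 0)
})

test_that("mask round-trips through a rigid transform stay close", {
  spec <- phantom_spec()
  tpl <- build_template(spec)
  mask <- (tpl$hab_left | tpl$hab_right) + 0
  expect_gte(sum(mask), 30)
  set.seed(33)
  for (i in 1:5) {
    ang <- runif(1, -0.12, 0.12)  # ~7 degrees
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
    tf <- rigid_transform(R, runif(3, -1.5, 1.5))
    fwd <- resample(mask, tf, tpl$affine, "nearest")
    back <- resample(fwd, invert_rigid(tf), tpl$affine, "nearest") > 0.5
    orig <- mask > 0.5
    dice <- 2 * sum(back & orig) / (sum(back) + sum(orig))
    expect_gte(dice, 0.8)
    expect_lte(abs(sum(back) / sum(orig) - 1), 0.15)
  }
})

test_that("ROI statistics match closed forms and a naive loop oracle", {
  d <- c(4L, 4L, 4L)
  m <- array(5, d)
  st <- roi_stats(m, array(TRUE, d), voxel_size = 0.8)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)

  vals <- array(0, d); vals[1, 1, 1:3] <- c(1, 2, 3)
  mask <- array(FALSE, d); mask[1, 1, 1:3] <- TRUE
  st <- roi_stats(vals, mask, voxel_size = 1)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2 / 3))
  st2 <- roi_stats(vals, mask, voxel_size = 1, sd_type = "sample")
  expect_equal(st2$sd, 1)

  # volume arithmetic: 40 voxels at 0.8 mm iso
  mask40 <- array(FALSE, c(10L, 10L, 10L)); mask40[1:40] <- TRUE
  expect_equal(roi_stats(array(1, c(10L, 10L, 10L)), mask40, 0.8)$volume_mm3,
               20.48)

  # naive loop oracle on random data
  set.seed(34)
  vol <- array(rnorm(4^3), d)
  mask <- array(runif(4^3) > 0.5, d)
  st <- roi_stats(vol, mask, voxel_size = 0.8)
  acc <- c(); n <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    if (mask[i, j, k]) { acc <- c(acc, vol[i, j, k]); n <- n + 1 }
  expect_identical(st$mean, mean(acc))
  expect_identical(st$sd, sqrt(mean((acc - mean(acc))^2)))
  expect_identical(st$n_voxels, as.integer(n))
  expect_error(roi_stats(vol, array(FALSE, d)), "empty")
})

test_that("volumetry and brain-normalised volume follow the definitions", {
  d <- c(80L, 80L, 80L)  # 512000 voxels at 1 mm
  probs <- list(WM = array(0.5, d), GM = array(0.3, d),
                CSF = array(0.05, d))
  probs$WM[1:400000] <- 0.95; probs$GM[1:400000] <- 0.05
  probs$CSF[1:400000] <- 0
  # summed rule: first 400000 voxels are brain (0.95+0.05 > 0.9)
  left <- array(FALSE, d); left[1:20] <- TRUE
  right <- array(FALSE, d); right[21:38] <- TRUE
  rep <- habenula_volumes(left, right, probs, voxel_size = 1)
  expect_equal(rep$vol_left_mm3, 20)
  expect_equal(rep$vol_right_mm3, 18)
  expect_equal(rep$vol_mean_mm3, 19)
  expect_equal(rep$brain_vol_mm3, 400000)
  expect_equal(rep$vol_norm_pct, 9.5e-3)

  # per-class rule differs when no single class crosses the threshold
  probs2 <- list(WM = array(0.5, d), GM = array(0.45, d),
                 CSF = array(0.05, d))
  rs <- habenula_volumes(left, right, probs2, 1, brain_rule = "sum")
  expect_equal(rs$brain_vol_mm3, prod(d))
  expect_error(habenula_volumes(left, right, probs2, 1,
                                brain_rule = "per_class"), "empty brain")

  # zero-volume habenula gives normalised 0
  none <- array(FALSE, d)
  expect_equal(habenula_volumes(none, none, probs, 1)$vol_norm_pct, 0)
  expect_error(habenula_volumes(left, left, probs, 1), "overlap")
})

test_that("ROI statistics survive the AC-PC reorientation round-trip", {
  # the manual-workflow cost: stats on round-tripped masks move < 2%
  spec <- phantom_spec()
  tpl <- build_template(spec)
  for (i in c(2, 4)) {
    s <- sample_subject(tpl, spec, i)
    hab <- s$hab_left | s$hab_right
    rt <- habmpm:::acpc_roundtrip_mask(hab, s$ac, s$pc, s$affine)
    st0 <- roi_stats(s$R1, hab, spec$voxel_size)
    st1 <- roi_stats(s$R1, rt, spec$voxel_size)
    expect_lt(abs(st1$mean / st0$mean - 1), 0.02)
  }
})
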