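# array sampling (nearest / trilinear / cubic), Gaussian smoothing and
# binary morphology on 3D volumes

# Sample a 3D array at fractional 1-based voxel coordinates (n x 3).
# nearest/trilinear treat out-of-grid samples as `outside`; cubic uses
# Catmull-Rom weights with clamped (replicated) borders, suitable for
# upsampling smooth fields. Coordinates within 1e-9 of an integer are
# snapped so that identity resampling is bit-exact.
sample_volume_at <- function(vol, ijk, method = c("trilinear", "nearest", "cubic"),
                             outside = 0) {
  method <- match.arg(method)
  d <- dim(vol)
  snap <- round(ijk)
  near <- abs(ijk - snap) < 1e-9
  ijk[near] <- snap[near]

  if (method == "nearest") {
    r <- round(ijk)
    inside <- r[, 1] >= 1 & r[, 1] <= d[1] & r[, 2] >= 1 & r[, 2] <= d[2] &
      r[, 3] >= 1 & r[, 3] <= d[3]
    out <- rep(outside, nrow(ijk))
    idx <- (r[inside, 3] - 1) * d[1] * d[2] + (r[inside, 2] - 1) * d[1] +
      r[inside, 1]
    out[inside] <- vol[idx]
    return(out)
  }

  if (method == "trilinear") {
    f <- floor(ijk)
    w <- ijk - f
    out <- rep(outside, nrow(ijk))
    acc <- numeric(nrow(ijk))
    valid <- rep(TRUE, nrow(ijk))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
        (if (dy) w[, 2] else 1 - w[, 2]) *
        (if (dz) w[, 3] else 1 - w[, 3])
      cx <- f[, 1] + dx; cy <- f[, 2] + dy; cz <- f[, 3] + dz
      inside <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] &
        cz >= 1 & cz <= d[3]
      use <- wt > 0
      valid <- valid & (inside | !use)
      vals <- numeric(nrow(ijk))
      ok <- inside & use
      if (any(ok))
        vals[ok] <- vol[(cz[ok] - 1) * d[1] * d[2] + (cy[ok] - 1) * d[1] + cx[ok]]
      acc <- acc + wt * vals
    }
    out[valid] <- acc[valid]
    return(out)
  }

  # Catmull-Rom cubic, clamped borders
  cr_w <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(`-1` = (-t3 + 2 * t2 - t) / 2,
         `0` = (3 * t3 - 5 * t2 + 2) / 2,
         `1` = (-3 * t3 + 4 * t2 + t) / 2,
         `2` = (t3 - t2) / 2)
  }
  base <- floor(ijk)
  t <- ijk - base
  wx <- cr_w(t[, 1]); wy <- cr_w(t[, 2]); wz <- cr_w(t[, 3])
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  acc <- numeric(nrow(ijk))
  offs <- c(-1, 0, 1, 2)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    wt <- wx[[as.character(ox)]] * wy[[as.character(oy)]] * wz[[as.character(oz)]]
    cx <- clamp(base[, 1] + ox, d[1])
    cy <- clamp(base[, 2] + oy, d[2])
    cz <- clamp(base[, 3] + oz, d[3])
    acc <- acc + wt * vol[(cz - 1) * d[1] * d[2] + (cy - 1) * d[1] + cx]
  }
  acc
}

# destination voxel centres -> world -> source voxel coords -> sample
resample_world <- function(src, src_affine, dst_world, method = "trilinear",
                           outside = 0) {
  ijk <- world_to_ijk(dst_world, src_affine)
  sample_volume_at(src, ijk, method = method, outside = outside)
}

# Separable Gaussian smoothing; fwhm in mm, zero outside the grid.
smooth_gaussian <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(vol)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (o in (-r):r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      m[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    m
  }
  # axis 1
  v <- band(d[1]) %*% matrix(vol, d[1])
  vol <- array(v, d)
  # axis 2
  p <- aperm(vol, c(2, 1, 3))
  v <- band(d[2]) %*% matrix(p, d[2])
  vol <- aperm(array(v, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  p <- aperm(vol, c(3, 1, 2))
  v <- band(d[3]) %*% matrix(p, d[3])
  aperm(array(v, d[c(3, 1, 2)]), c(2, 3, 1))
}

# binary dilation by one voxel, 6- or 26-connected structuring element
dilate_mask <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    s <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    else { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    s[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    s
  }
  if (connectivity == 6L) {
    for (ax in 1:3) for (by in c(1, -1)) out <- out | shift(mask, ax, by)
  } else if (connectivity == 26L) {
    cur <- mask
    for (ax in 1:3) {
      nxt <- cur
      for (by in c(1, -1)) nxt <- nxt | shift(cur, ax, by)
      cur <- nxt
    }
    out <- cur
  } else stopf("connectivity must be 6 or 26")
  out
}
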