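#' Joint ESTATICS fit of R2* and per-weighting intercepts
#'
#' Fits, per voxel, ordinary least squares on
#' `ln S_w(TE_n) = ln S_w(0) - R2* TE_n` jointly over all weightings and
#' echoes, with a single shared decay rate R2* and one intercept per
#' weighting (the ESTATICS model). Pooling the echo trains of all three
#' weightings stabilises the decay estimate; the MT-weighted train simply
#' contributes fewer echoes.
#'
#' Voxels with any non-positive or non-finite signal are excluded from
#' the valid mask (their count is reported via a message and stored).
#' Negative fitted decay rates are clamped to zero by default, with
#' intercepts refitted under the clamped slope.
#'
#' @param volumes an `echo_volume_set` ([simulate_flash()] output or the
#'   `stacks`/`protocol` subset of [read_subject()]).
#' @param clamp_negative clamp negative R2* estimates to 0 (default TRUE).
#' @return an `estatics_fit` object: `intercepts` (named list of
#'   S_w(TE=0) volumes, signal units), `r2s` (1/s), `rss` (residual sum
#'   of squares of log-signals), `mask`, exclusion/clamp counts.
#' @examples
#' spec <- phantom_spec()
#' vols <- simulate_flash(build_template(spec), mpm_protocol(), spec)
#' fit <- estatics_fit(vols)
#' range(fit$r2s[fit$mask])
#' @export
estatics_fit <- function(volumes, clamp_negative = TRUE) {
  stacks <- volumes$stacks
  proto <- volumes$protocol
  if (length(stacks) == 0L) stopf("no echo stacks to fit")
  dims <- dim(stacks[[1]])[1:3]
  nvox <- prod(dims)

  te_list <- lapply(names(stacks), function(w) proto[[w]]$te_ms / 1000)
  names(te_list) <- names(stacks)
  for (w in names(stacks)) {
    if (dim(stacks[[w]])[4] != length(te_list[[w]]))
      stopf("%s: echo count does not match TE list", w)
    if (length(te_list[[w]]) < 2L && length(stacks) == 1L)
      stopf("need at least 2 echoes to fit a decay")
    if (length(unique(unlist(te_list))) < 2L)
      stopf("singular design: all echo times equal")
  }

  any_signal <- rep(FALSE, nvox)
  mask <- rep(TRUE, nvox)
  for (w in names(stacks)) {
    m <- matrix(stacks[[w]], nvox)
    pos <- m > 0 & is.finite(m)
    any_signal <- any_signal | rowSums(m != 0, na.rm = TRUE) > 0
    mask <- mask & rowSums(pos) == ncol(m)
  }
  n_excluded <- sum(any_signal & !mask)
  if (n_excluded > 0)
    message(sprintf("estatics_fit: %d voxels with non-positive signal excluded",
                    n_excluded))

  idx <- which(mask)
  sxy <- numeric(length(idx))
  sxx <- 0
  ybars <- list(); tbars <- list()
  for (w in names(stacks)) {
    y <- log(matrix(stacks[[w]], nvox)[idx, , drop = FALSE])
    t <- te_list[[w]]
    tbar <- mean(t)
    ybar <- rowMeans(y)
    tc <- t - tbar
    sxx <- sxx + sum(tc^2)
    sxy <- sxy + as.vector(y %*% tc)
    ybars[[w]] <- ybar; tbars[[w]] <- tbar
  }
  slope <- sxy / sxx          # d(lnS)/dTE = -R2*
  r2s_v <- -slope
  n_clamped <- 0L
  if (clamp_negative) {
    neg <- r2s_v < 0
    n_clamped <- sum(neg)
    r2s_v[neg] <- 0
  }

  intercepts <- list()
  rss_v <- numeric(length(idx))
  for (w in names(stacks)) {
    b <- ybars[[w]] + r2s_v * tbars[[w]]
    y <- log(matrix(stacks[[w]], nvox)[idx, , drop = FALSE])
    resid <- y - outer(b, rep(1, length(te_list[[w]]))) +
      outer(r2s_v, te_list[[w]])
    rss_v <- rss_v + rowSums(resid^2)
    s0 <- array(NA_real_, dims); s0[idx] <- exp(b)
    intercepts[[w]] <- s0
  }

  r2s <- array(NA_real_, dims); r2s[idx] <- r2s_v
  rss <- array(NA_real_, dims); rss[idx] <- rss_v
  structure(list(intercepts = intercepts, r2s = r2s, rss = rss,
                 mask = array(mask, dims),
                 n_excluded = n_excluded, n_clamped = n_clamped,
                 te_s = te_list),
            class = "estatics_fit")
}

#' @export
print.estatics_fit <- function(x, ...) {
  cat(sprintf("ESTATICS joint fit: %d valid voxels (%d excluded, %d clamped)\n",
              sum(x$mask), x$n_excluded, x$n_clamped))
  cat(sprintf("  weightings: %s; R2* median %.2f 1/s\n",
              paste(names(x$intercepts), collapse = ", "),
              median(x$r2s[x$mask])))
  invisible(x)
}
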