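# joint log-linear decay fit against closed forms and a generic
# least-squares oracle

make_stack <- function(s0, r2s, te_ms, dims = dim(s0)) {
  st <- array(0, c(dims, length(te_ms)))
  for (n in seq_along(te_ms))
    st[, , , n] <- s0 * exp(-(te_ms[n] / 1000) * r2s)
  st
}

test_that("a single mono-exponential decay is recovered exactly", {
  proto <- mpm_protocol()
  dims <- c(2L, 2L, 2L)
  s0 <- array(100, dims)
  r2s <- array(20, dims)  # 0.020 per ms
  vols <- list(stacks = list(PDw = make_stack(s0, r2s, proto$PDw$te_ms)),
               protocol = proto)
  fit <- estatics_fit(vols)
  expect_equal(as.vector(fit$intercepts$PDw), rep(100, 8), tolerance = 1e-10)
  expect_equal(as.vector(fit$r2s), rep(20, 8), tolerance = 1e-10)
  expect_true(all(fit$mask))
  expect_equal(max(fit$rss), 0, tolerance = 1e-18)
})

test_that("three weightings with a common decay are recovered exactly", {
  proto <- mpm_protocol()
  dims <- c(3L, 3L, 3L)
  r2s <- array(19.11, dims)
  vols <- list(stacks = list(
    T1w = make_stack(array(100, dims), r2s, proto$T1w$te_ms),
    PDw = make_stack(array(80, dims), r2s, proto$PDw$te_ms),
    MTw = make_stack(array(60, dims), r2s, proto$MTw$te_ms)),
    protocol = proto)
  fit <- estatics_fit(vols)
  expect_equal(as.vector(fit$r2s), rep(19.11, 27), tolerance = 1e-10)
  expect_equal(mean(fit$intercepts$T1w), 100, tolerance = 1e-10)
  expect_equal(mean(fit$intercepts$PDw), 80, tolerance = 1e-10)
  expect_equal(mean(fit$intercepts$MTw), 60, tolerance = 1e-10)
})

test_that("the joint fit equals a generic per-voxel least-squares oracle", {
  set.seed(101)
  proto <- mpm_protocol()
  dims <- c(10L, 10L, 10L)
  n <- prod(dims)
  s0 <- list(T1w = array(runif(n, 50, 150), dims),
             PDw = array(runif(n, 50, 150), dims),
             MTw = array(runif(n, 30, 120), dims))
  r2s <- array(runif(n, 5, 40), dims)
  stacks <- lapply(names(s0), function(w) {
    st <- make_stack(s0[[w]], r2s, proto[[w]]$te_ms)
    st * exp(array(rnorm(length(st), 0, 0.05), dim(st)))  # log-normal noise
  })
  names(stacks) <- names(s0)
  fit <- estatics_fit(list(stacks = stacks, protocol = proto))

  # independent oracle: stack all echoes and solve the same linear model
  # with lm() per voxel
  te_all <- unlist(lapply(names(stacks), function(w) proto[[w]]$te_ms / 1000))
  w_all <- factor(rep(names(stacks),
                      vapply(names(stacks), function(w)
                        length(proto[[w]]$te_ms), 1L)),
                  levels = names(stacks))
  ymat <- do.call(cbind, lapply(stacks, function(st) matrix(st, n)))
  check <- sample.int(n, 1000)
  for (v in check) {
    cf <- coef(lm(log(ymat[v, ]) ~ 0 + w_all + te_all))
    expect_equal(fit$r2s[v], unname(-cf[["te_all"]]), tolerance = 1e-10)
    expect_equal(fit$intercepts$T1w[v], unname(exp(cf[["w_allT1w"]])),
                 tolerance = 1e-10)
    expect_equal(fit$intercepts$MTw[v], unname(exp(cf[["w_allMTw"]])),
                 tolerance = 1e-10)
  }
})

test_that("non-positive voxels are excluded and degenerate designs rejected", {
  proto <- mpm_protocol()
  dims <- c(2L, 2L, 2L)
  st <- make_stack(array(100, dims), array(20, dims), proto$PDw$te_ms)
  st[1, 1, 1, 3] <- 0
  st[2, 2, 2, 1] <- -5
  expect_message(
    fit <- estatics_fit(list(stacks = list(PDw = st), protocol = proto)),
    "2 voxels")
  expect_identical(sum(!fit$mask), 2L)
  expect_true(is.na(fit$r2s[1, 1, 1]))

  proto_bad <- proto
  proto_bad$T1w$te_ms <- 5; proto_bad$PDw$te_ms <- 5; proto_bad$MTw$te_ms <- 5
  same_te <- lapply(c("T1w", "PDw", "MTw"), function(w)
    make_stack(array(100, dims), array(20, dims), 5))
  names(same_te) <- c("T1w", "PDw", "MTw")
  expect_error(estatics_fit(list(stacks = same_te, protocol = proto_bad)),
               "singular")
})

test_that("negative decays are clamped to zero by default", {
  proto <- mpm_protocol()
  dims <- c(2L, 2L, 2L)
  growing <- make_stack(array(100, dims), array(-3, dims), proto$PDw$te_ms)
  fit <- estatics_fit(list(stacks = list(PDw = growing), protocol = proto))
  expect_true(all(fit$r2s == 0))
  expect_identical(fit$n_clamped, 8L)
  raw <- estatics_fit(list(stacks = list(PDw = growing), protocol = proto),
                      clamp_negative = FALSE)
  expect_equal(as.vector(raw$r2s), rep(-3, 8), tolerance = 1e-10)
})
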