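# The learnable spatial histogram layer: radial-basis binning, 1x1
# reduction, windowed averaging, and its gradients.

test_that("radial-basis bin response follows its closed form", {
  expect_equal(rbf_bin_response(0.7, 0.7, 5.0), 1.0)
  expect_equal(rbf_bin_response(3.2, -1.0, 0.0), 1.0)
  for (gamma in c(0.5, 1, 4, -2)) {
    expect_equal(rbf_bin_response(0.3 + 1 / gamma, 0.3, gamma), exp(-1))
  }
  # symmetric in (x - mu) and in the sign of gamma; strictly decreasing
  x <- seq(-2, 2, length.out = 41)
  expect_equal(rbf_bin_response(x, 0, 1.3), rbf_bin_response(-x, 0, 1.3))
  expect_equal(rbf_bin_response(x, 0.2, 1.7), rbf_bin_response(x, 0.2, -1.7))
  r <- rbf_bin_response(seq(0, 3, by = 0.1), 0, 2)
  expect_true(all(diff(r) < 0))
  expect_error(rbf_bin_response(NaN, 0, 1), "finite")
})

test_that("1x1 reduction is an exact per-pixel linear map", {
  # identity projection returns the input unchanged
  x <- rand_hwc(5, 4, 3, seed = 1)
  expect_equal(reduce_channels(x, diag(3)), x)
  # random projection equals the nested-loop oracle
  set.seed(2)
  x <- rand_hwc(5, 5, 8)
  w <- matrix(rnorm(16), 8, 2)
  expect_equal(reduce_channels(x, w), oracle_reduce(x, w), tolerance = 1e-12)
  # spatial dims unchanged, channel mismatch rejected
  expect_equal(dim(reduce_channels(x, w)), c(5, 5, 2))
  expect_error(reduce_channels(x, matrix(0, 4, 2)), "channels")
})

test_that("local histogram matches the independent nested-loop oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    H <- sample(3:7, 1); W <- sample(3:7, 1)
    K <- sample(1:2, 1); B <- sample(1:3, 1)
    S <- sample(1:3, 1); T <- sample(1:3, 1)
    x <- array(runif(H * W * K, -2, 2), c(H, W, K))
    mu <- matrix(runif(B * K, -1, 1), B, K)
    gamma <- matrix(runif(B * K, -2, 2), B, K)
    got <- local_histogram(x, bin_params(mu, gamma), c(S, T))
    want <- oracle_local_hist(x, mu, gamma, S, T)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("degenerate inputs give unit responses", {
  bp <- bin_params(matrix(c(-1, 0.5), 2, 1), matrix(c(3, 3), 2, 1))
  # constant input at a bin centre: that bin's map is exactly 1
  x <- array(0.5, c(6, 6, 1))
  h <- local_histogram(x, bp, c(2, 2))
  expect_equal(h[, , 2], matrix(1, 6, 6))
  expect_true(all(h > 0 & h <= 1))
  # all-zero widths degenerate to constant response 1 everywhere
  bp0 <- bin_params(matrix(c(-1, 0.5), 2, 1), matrix(0, 2, 1))
  h0 <- local_histogram(rand_hwc(6, 6, 1, seed = 3), bp0, c(2, 2))
  expect_equal(h0, array(1, c(6, 6, 2)))
})

test_that("output is invariant to the sign of any width entry", {
  set.seed(7)
  x <- rand_hwc(6, 6, 2)
  mu <- matrix(rnorm(6), 3, 2)
  gamma <- matrix(runif(6, 0.5, 2), 3, 2)
  g2 <- gamma
  g2[2, 1] <- -g2[2, 1]
  g2[3, 2] <- -g2[3, 2]
  expect_identical(local_histogram(x, bin_params(mu, gamma), c(2, 2)),
                   local_histogram(x, bin_params(mu, g2), c(2, 2)))
})

test_that("histogram block conserves channels and rejects bad configs", {
  cfg <- histogram_config(64, bins = 16, reduced_channels = 4)
  set.seed(4)
  x <- rand_hwc(8, 8, 64)
  params <- list(weights = matrix(rnorm(64 * 4, sd = 0.2), 64, 4),
                 bins = init_bin_params(16, 4))
  h <- histogram_block(x, cfg, params)
  expect_equal(dim(h), c(8, 8, 64))
  expect_true(all(h > 0 & h <= 1))
  expect_error(histogram_config(64, bins = 16, reduced_channels = 5),
               "channel conservation")
  expect_error(histogram_block(rand_hwc(8, 8, 32), cfg, params), "channels")
})

test_that("histogram block composes reduction and binning", {
  set.seed(5)
  x <- rand_hwc(8, 8, 16)
  cfg <- histogram_config(16, bins = 4, reduced_channels = 4)
  params <- list(weights = matrix(rnorm(64, sd = 0.3), 16, 4),
                 bins = init_bin_params(4, 4))
  got <- histogram_block(x, cfg, params)
  r <- oracle_reduce(x, params$weights)
  want <- oracle_local_hist(r, params$bins$centers, params$bins$widths, 2, 2)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("pool mode restores the input spatial size", {
  cfg <- histogram_config(4, bins = 2, reduced_channels = 2,
                          spatial_mode = "pool")
  set.seed(6)
  x <- rand_hwc(8, 8, 4)
  params <- list(weights = matrix(rnorm(8, sd = 0.4), 4, 2),
                 bins = init_bin_params(2, 2))
  h <- histogram_block(x, cfg, params)
  expect_equal(dim(h), c(8, 8, 4))
  expect_true(all(h > 0 & h <= 1))
})

test_that("histogram-block gradients match finite differences", {
  # bin centres, widths and the 1x1 weights are all trained by
  # backpropagation, so their analytic gradients must agree with central
  # finite differences of a scalar loss
  set.seed(8)
  x <- rand_hwc(6, 6, 4)
  cfg <- histogram_config(4, bins = 2, reduced_channels = 2)
  w <- matrix(rnorm(8, sd = 0.5), 4, 2)
  mu <- matrix(rnorm(4), 2, 2)
  gamma <- matrix(runif(4, 0.5, 1.5), 2, 2)
  tgt <- array(runif(6 * 6 * 4), c(6, 6, 4))
  loss <- function(w, mu, gamma) {
    f <- joshuaseg:::hist_block_fwd(x, cfg, w, mu, gamma)
    sum((f$out - tgt)^2) / 2
  }
  f <- joshuaseg:::hist_block_fwd(x, cfg, w, mu, gamma)
  g <- joshuaseg:::hist_block_bwd(x, cfg, w, mu, gamma, f, f$out - tgt)
  h <- 1e-6
  check <- function(arr, name) {
    for (i in seq_along(arr)) {
      up <- arr; up[i] <- up[i] + h
      dn <- arr; dn[i] <- dn[i] - h
      fd <- switch(name,
        w = (loss(up, mu, gamma) - loss(dn, mu, gamma)) / (2 * h),
        mu = (loss(w, up, gamma) - loss(w, dn, gamma)) / (2 * h),
        gamma = (loss(w, mu, up) - loss(w, mu, dn)) / (2 * h))
      an <- switch(name, w = g$gw[i], mu = g$gmu[i], gamma = g$ggamma[i])
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-5), 1e-3)
    }
  }
  check(w, "w"); check(mu, "mu"); check(gamma, "gamma")
})
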