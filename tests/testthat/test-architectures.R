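# Construction and wiring of the five comparison networks.

test_that("builds are reproducible under a fixed seed", {
  for (v in c("unet", "joshua_plus")) {
    m1 <- build_model(tiny_spec(v), seed = 11)
    m2 <- build_model(tiny_spec(v), seed = 11)
    expect_identical(m1$params, m2$params)
    m3 <- build_model(tiny_spec(v), seed = 12)
    expect_false(identical(m3$params, m1$params))
  }
})

test_that("forward pass maps RGB input to an in-range probability map", {
  m <- build_model(tiny_spec("unet"), seed = 0)
  x <- array(0, c(32, 32, 3))
  fw <- joshuaseg:::model_forward(m, x)
  expect_equal(dim(fw$prob), c(32, 32, 1))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # inputs not divisible by 2^depth are rejected, never silently cropped
  expect_error(joshuaseg:::model_forward(m, array(0, c(30, 32, 3))),
               "resize required")
})

test_that("multiplicative variants halve decoder input channels", {
  mu <- build_model(model_spec("unet", depth = 3, base_channels = 8), 0)
  mp <- build_model(model_spec("unet_plus", depth = 3, base_channels = 8), 0)
  for (j in 1:3) {
    wu <- dim(mu$params[[sprintf("up%d.c1.w", j)]])
    wp <- dim(mp$params[[sprintf("up%d.c1.w", j)]])
    expect_equal(wp[3] * 2L, wu[3])      # input channels halved
    expect_equal(wp[4], wu[4])           # output channels unchanged
  }
})

test_that("parameter counts show the ~18% multiplicative-fusion reduction", {
  n_unet <- count_parameters(build_model(model_spec("unet"), 0))
  n_up <- count_parameters(build_model(model_spec("unet_plus"), 0))
  n_j <- count_parameters(build_model(model_spec("joshua"), 0))
  n_jp <- count_parameters(build_model(model_spec("joshua_plus"), 0))
  expect_lt(n_up, n_unet)
  expect_lt(n_jp, n_j)
  expect_gt(n_j, n_unet)                 # histogram params are extra
  expect_equal(n_up / n_unet, 0.82, tolerance = 0.025)
  reduction <- 100 * (1 - n_jp / n_j)
  expect_gt(reduction, 16); expect_lt(reduction, 20)
})

test_that("count_parameters sums every trainable array", {
  m <- build_model(tiny_spec("joshua"), 0)
  expect_identical(count_parameters(m),
                   sum(vapply(m$params, length, integer(1))))
  # joshua variants include bin centres/widths and reducers
  expect_true(any(grepl("hist", names(m$params))))
})

test_that("concatenation fusion stacks channels losslessly", {
  set.seed(13)
  a <- rand_hwc(4, 4, 2); b <- rand_hwc(4, 4, 2)
  f <- fuse_concat(a, b)
  expect_equal(dim(f), c(4, 4, 4))
  sp <- joshuaseg:::split_channels(f, 2)
  expect_identical(sp[[1]], a)
  expect_identical(sp[[2]], b)
  expect_error(fuse_concat(a, rand_hwc(5, 4, 2)), "spatial")
})

test_that("multiplicative fusion is the exact Hadamard product", {
  set.seed(14)
  h <- rand_hwc(5, 5, 3); x <- rand_hwc(5, 5, 3)
  expect_identical(fuse_multiply(array(1, dim(x)), x), x)
  expect_equal(fuse_multiply(array(0, dim(x)), x), array(0, dim(x)))
  got <- fuse_multiply(h, x)
  for (ch in 1:3) for (r in 1:5) for (cc in 1:5) {
    expect_identical(got[r, cc, ch], h[r, cc, ch] * x[r, cc, ch])
  }
  expect_error(fuse_multiply(h, rand_hwc(5, 5, 2)), "identical shapes")
})

test_that("attention gate produces bounded coefficients applied to the encoder map", {
  set.seed(15)
  params <- list(wg_w = array(rnorm(4 * 2, sd = 0.3), c(1, 1, 4, 2)),
                 wg_b = rnorm(2, sd = 0.1),
                 wx_w = array(rnorm(4 * 2, sd = 0.3), c(1, 1, 4, 2)),
                 psi_w = array(rnorm(2, sd = 0.3), c(1, 1, 2, 1)),
                 psi_b = 0.1)
  for (i in 1:20) {
    e <- rand_hwc(6, 6, 4); u <- rand_hwc(6, 6, 4)
    g <- attention_gate(e, u, params)
    expect_true(all(g$coefficients > 0 & g$coefficients < 1))
    expect_equal(g$out, e * c(g$coefficients), tolerance = 1e-12)
  }
  # zero projections: coefficients constant at sigmoid(psi_b)
  z <- params
  z$psi_w[] <- 0
  g <- attention_gate(rand_hwc(6, 6, 4), rand_hwc(6, 6, 4), z)
  expect_equal(unique(c(g$coefficients)), 1 / (1 + exp(-0.1)), tolerance = 1e-12)
})

test_that("prediction thresholds at 0.5 with ties going positive", {
  m <- build_model(tiny_spec("unet"), 0)
  # zero head -> logits 0 -> probability exactly 0.5 everywhere
  m$params[["outc.w"]][] <- 0
  m$params[["outc.b"]][] <- 0
  x <- rand_hwc(16, 16, 3, seed = 16)
  expect_true(all(predict_mask(m, x, threshold = 0.5) == 1L))
  expect_true(all(predict_mask(m, x, threshold = 0.5 + 1e-9) == 0L))
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(17)
  x <- rand_hwc(16, 16, 3)
  y <- matrix(rbinom(256, 1, 0.4), 16, 16)
  for (v in c("unet", "unet_plus", "attention_unet", "joshua", "joshua_plus")) {
    m <- build_model(tiny_spec(v), seed = 7)
    lg <- joshuaseg:::loss_and_grads(m, x, y, pos_weight = 2)
    loss_at <- function(mm) joshuaseg:::loss_and_grads(mm, x, y, 2)$loss
    set.seed(18)
    h <- 1e-6
    for (nm in sample(names(m$params), 6)) {
      for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
        up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + h
        dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - h
        fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
        an <- lg$grads[[nm]][i]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-5), 1e-3)
      }
    }
  }
})

test_that("checkpoints round-trip and revalidate the spec", {
  m <- build_model(tiny_spec("joshua_plus"), 3)
  m$params[["outc.b"]][] <- 0.123
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$spec), unclass(m$spec))
  # forward passes agree exactly
  x <- rand_hwc(16, 16, 3, seed = 19)
  expect_identical(predict_mask(m, x), predict_mask(m2, x))
  # corrupted spec is rejected on load (bins no longer divide the channels)
  ck <- readRDS(path)
  ck$spec$base_channels <- 5
  bad <- tempfile(fileext = ".ckpt")
  saveRDS(ck, bad)
  expect_error(load_checkpoint(bad))
})
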