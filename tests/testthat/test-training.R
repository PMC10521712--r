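# Loss, optimiser mechanics, early stopping and the experiment harness.

test_that("weighted BCE matches its closed forms and the loop oracle", {
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  p <- pmin(pmax(y, 1e-7), 1 - 1e-7)
  expect_lt(weighted_bce(p, y, 3), 1e-5)               # p == y: near zero
  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  expect_equal(weighted_bce(matrix(0.5, 8, 8), half, 1), log(2))
  set.seed(51)
  prob <- matrix(runif(64, 0.01, 0.99), 8, 8)
  expect_equal(weighted_bce(prob, y, 3), oracle_wbce(prob, y, 3),
               tolerance = 1e-6)
  expect_gte(weighted_bce(prob, y, 1), 0)
  # monotone in pos_weight whenever positives exist with p < 1
  expect_gt(weighted_bce(prob, y, 3), weighted_bce(prob, y, 1))
  expect_error(weighted_bce(prob * 2, y), "\\[0, 1\\]")
  expect_error(weighted_bce(prob, y * 0.5), "binary")
})

test_that("the logit gradient of weighted BCE is exact", {
  set.seed(52)
  z <- matrix(rnorm(16), 4, 4)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  p <- 1 / (1 + exp(-z))
  g <- joshuaseg:::wbce_grad_logits(p, y, 3)
  h <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    fd <- (weighted_bce(1 / (1 + exp(-zp)), y, 3) -
           weighted_bce(1 / (1 + exp(-zm)), y, 3)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("gradient clipping bounds values or the global norm", {
  g <- list(a = c(-5, 0.05, 2), b = matrix(c(0.2, -0.01), 1))
  cv <- joshuaseg:::clip_grads(g, 0.1, "value")
  expect_true(all(abs(unlist(cv)) <= 0.1))
  expect_equal(cv$a[2], 0.05)                          # small values untouched
  cn <- joshuaseg:::clip_grads(g, 0.1, "norm")
  expect_equal(sqrt(sum(unlist(cn)^2)), 0.1, tolerance = 1e-12)
  small <- list(a = c(0.01, 0.02))
  expect_identical(joshuaseg:::clip_grads(small, 0.1, "norm"), small)
})

test_that("zero learning rate leaves parameters unchanged", {
  pairs <- tiny_dataset(6, size = 16, seed = 53)
  m0 <- build_model(tiny_spec(base = 4), seed = 1)
  cfg <- train_config(epochs = 2, learning_rate = 0, batch_size = 2,
                      patience = 1, repeats_per_epoch = 1)
  rec <- train_one(tiny_spec(base = 4), pairs[1:4], pairs[5:6], cfg, seed = 1)
  expect_equal(rec$model$params, m0$params)
})

test_that("training is deterministic under a fixed seed", {
  pairs <- tiny_dataset(8, size = 16, seed = 54)
  cfg <- train_config(epochs = 3, batch_size = 2, patience = 2,
                      repeats_per_epoch = 1)
  r1 <- train_one(tiny_spec(base = 4), pairs[1:6], pairs[7:8], cfg, seed = 5)
  r2 <- train_one(tiny_spec(base = 4), pairs[1:6], pairs[7:8], cfg, seed = 5)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  r3 <- train_one(tiny_spec(base = 4), pairs[1:6], pairs[7:8], cfg, seed = 6)
  expect_false(identical(r3$history, r1$history))
})

test_that("early stopping halts after patience and restores the best epoch", {
  pairs <- tiny_dataset(8, size = 16, seed = 55)
  cfg <- train_config(epochs = 30, batch_size = 4, patience = 3,
                      repeats_per_epoch = 1, learning_rate = 0.05)
  rec <- train_one(tiny_spec("unet", base = 4), pairs[1:6], pairs[7:8], cfg,
                   seed = 2)
  expect_lte(rec$stopped_epoch, cfg$epochs)
  expect_lte(rec$stopped_epoch - rec$best_epoch, cfg$patience)
  if (rec$stopped_epoch < cfg$epochs) {
    expect_equal(rec$stopped_epoch - rec$best_epoch, cfg$patience)
  }
  # restored parameters reproduce the best validation loss
  vl <- joshuaseg:::validation_loss(rec$model, pairs[7:8], cfg$pos_weight)
  expect_equal(vl, rec$best_val_loss, tolerance = 1e-10)
  expect_equal(rec$best_val_loss, min(rec$history$val_loss))
})

test_that("experiment bookkeeping yields one record per variant-fold-seed", {
  pairs <- tiny_dataset(8, size = 16, seed = 56)
  folds <- make_folds(names(pairs), scheme = "random_kfold", k = 2, seed = 1)
  cfg <- train_config(epochs = 2, batch_size = 4, patience = 1,
                      repeats_per_epoch = 1)
  specs <- list(tiny_spec("unet", base = 4), tiny_spec("unet_plus", base = 4))
  res <- run_experiment(specs, pairs, folds, cfg, seeds = 0)
  expect_length(res$records, 4)
  expect_setequal(unique(res$summary$variant), c("unet", "unet_plus"))
  expect_equal(nrow(res$summary), 14)    # 7 metrics x 2 variants
  # 1 variant x 5 folds x 3 seeds = 15 records
  folds5 <- make_folds(names(pairs), scheme = "random_kfold", k = 5, seed = 2)
  res15 <- run_experiment(list(tiny_spec("unet", base = 4)), pairs, folds5,
                          cfg, seeds = 0:2)
  expect_length(res15$records, 15)
})

test_that("every architecture variant learns the synthetic task at desk scale", {
  sp <- synthetic_spec(n_images = 40, height = 64, width = 64, seed = 321)
  pairs <- generate_synthetic_images(sp)
  train_set <- pairs[1:32]; val_set <- pairs[33:40]
  cfg <- train_config(epochs = 20, batch_size = 1, pos_weight = 3,
                      patience = 10, repeats_per_epoch = 2)
  poor <- generate_synthetic_images(
    synthetic_spec(n_images = 6, height = 64, width = 64,
                   adipose_fraction_range = c(0.001, 0.01),
                   n_blobs_range = c(1, 2), blob_axis_range = c(2, 4),
                   seed = 322))
  recalls <- c()
  for (v in c("unet", "unet_plus", "attention_unet", "joshua", "joshua_plus")) {
    spec <- model_spec(v, depth = 2, base_channels = 8, bins = 4)
    rec <- train_one(spec, train_set, val_set, cfg, seed = 0, fold = 1)
    expect_gt(mean(rec$metrics$dice), 0.8)
    # directional property on adipose-poor images: reported, not asserted
    pr <- vapply(poor, function(p) {
      seg_metrics(predict_mask(rec$model, p$image), p$mask)$recall
    }, numeric(1))
    recalls[v] <- mean(pr)
  }
  message(sprintf(
    "adipose-poor recall  unet=%.3f unet+=%.3f att=%.3f joshua=%.3f joshua+=%.3f",
    recalls["unet"], recalls["unet_plus"], recalls["attention_unet"],
    recalls["joshua"], recalls["joshua_plus"]))
  expect_length(recalls, 5)
})

test_that("interrupted experiments resume from saved records", {
  pairs <- tiny_dataset(6, size = 16, seed = 57)
  folds <- make_folds(names(pairs), scheme = "random_kfold", k = 2, seed = 1)
  cfg <- train_config(epochs = 2, batch_size = 3, patience = 1,
                      repeats_per_epoch = 1)
  out <- tempfile()
  res1 <- run_experiment(list(tiny_spec("unet", base = 4)), pairs, folds, cfg,
                         seeds = 0, out_dir = out)
  files <- list.files(out, full.names = TRUE)
  expect_length(files, 2)
  stamps <- file.mtime(files)
  Sys.sleep(1.1)
  res2 <- run_experiment(list(tiny_spec("unet", base = 4)), pairs, folds, cfg,
                         seeds = 0, out_dir = out)
  expect_identical(file.mtime(files), stamps)   # nothing retrained
  expect_equal(res2$summary, res1$summary)
})
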