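# Independent brute-force oracles, written against the definitions (not the
# package's vectorized/C++ code paths), plus small fixture builders.

# nested-loop evaluation of the windowed radial-basis histogram
oracle_local_hist <- function(x, mu, gamma, S, T) {
  H <- dim(x)[1]; W <- dim(x)[2]; K <- dim(x)[3]; B <- nrow(mu)
  lo_r <- (S - 1) %/% 2; lo_c <- (T - 1) %/% 2
  out <- array(0, c(H, W, B * K))
  for (k in 1:K) for (b in 1:B) for (r in 1:H) for (cc in 1:W) {
    acc <- 0
    for (s in 0:(S - 1)) for (t in 0:(T - 1)) {
      rr <- min(max(r - lo_r + s, 1), H)
      c2 <- min(max(cc - lo_c + t, 1), W)
      acc <- acc + exp(-gamma[b, k]^2 * (x[rr, c2, k] - mu[b, k])^2)
    }
    out[r, cc, (k - 1) * B + b] <- acc / (S * T)
  }
  out
}

# per-pixel 1x1 projection by explicit loops
oracle_reduce <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]; D <- dim(x)[3]; K <- ncol(w)
  out <- array(0, c(H, W, K))
  for (r in 1:H) for (cc in 1:W) for (k in 1:K) {
    out[r, cc, k] <- sum(x[r, cc, ] * w[, k])
  }
  out
}

# pixel-loop confusion counting and metrics
oracle_metrics <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# per-pixel weighted binary cross entropy by summation
oracle_wbce <- function(prob, truth, w) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(prob)) {
    p <- min(max(prob[i], eps), 1 - eps)
    total <- total + (-(w * truth[i] * log(p) + (1 - truth[i]) * log(1 - p)))
  }
  total / length(prob)
}

rand_hwc <- function(h, w, c, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * c, -1.5, 1.5), c(h, w, c))
}

tiny_spec <- function(variant = "joshua_plus", depth = 2, base = 4, bins = 2) {
  model_spec(variant, depth = depth, base_channels = base, bins = bins)
}

# small in-memory blob dataset for training tests
tiny_dataset <- function(n, size = 32, seed = 99, ...) {
  sp <- synthetic_spec(n_images = n, height = size, width = size,
                       adipose_fraction_range = c(0.01, 0.5),
                       n_blobs_range = c(1, 3), blob_axis_range = c(2, 4),
                       seed = seed, ...)
  pairs <- generate_synthetic_images(sp)
  names(pairs) <- vapply(pairs, `[[`, "", "id")
  pairs
}
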