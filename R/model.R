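#' Declarative specification of a segmentation network
#'
#' Describes one of the five comparison architectures completely enough to
#' rebuild it deterministically. All variants share the same encoder
#' (double 3x3 conv + ReLU per level, 2x2 max pooling, channels doubling
#' from `base_channels`, bottleneck kept at the deepest encoder width) and
#' decoder (bilinear upsampling, double conv); they differ only in what the
#' skip connections carry and how it is fused into the decoder:
#'
#' * `unet` — encoder map concatenated with the decoder map.
#' * `joshua` — histogram block applied to the encoder map, concatenated.
#' * `unet_plus` — encoder map fused by elementwise multiplication.
#' * `joshua_plus` — histogram-block output fused by multiplication.
#' * `attention_unet` — additive attention gate on the encoder map,
#'   concatenated.
#'
#' Multiplicative fusion halves the input channels of every decoder block,
#' which removes roughly 18% of the learnable parameters at the default
#' depth-4 / base-64 configuration.
#'
#' @param variant one of `"unet"`, `"unet_plus"`, `"attention_unet"`,
#'   `"joshua"`, `"joshua_plus"`.
#' @param depth number of encoder down-steps (default 4; plus a bottleneck).
#' @param base_channels channels at the first level (default 64).
#' @param bins histogram bins per reduced channel (joshua variants); must
#'   divide the channel count at every level, i.e. `base_channels`.
#' @param window histogram window `(S, T)`.
#' @param spatial_mode histogram spatial handling, see [histogram_config].
#' @param hist_span initial bin-centre span, see [init_bin_params].
#' @param in_channels input image channels (3 for RGB).
#' @param out_classes output classes (1, binary).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(variant = c("unet", "unet_plus", "attention_unet",
                                   "joshua", "joshua_plus"),
                       depth = 4, base_channels = 64,
                       bins = 16, window = c(2, 2),
                       spatial_mode = c("preserve", "pool"),
                       hist_span = c(-2, 2),
                       in_channels = 3, out_classes = 1) {
  variant <- match.arg(variant)
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(depth >= 1, base_channels >= 1, out_classes == 1)
  if (variant %in% c("joshua", "joshua_plus")) {
    if (is.null(bins) || bins < 1) {
      stop("joshua variants require a histogram configuration (`bins`)",
           call. = FALSE)
    }
    if (base_channels %% bins != 0) {
      stop(sprintf(
        "bins (%d) must divide the channel count at every level (base %d)",
        bins, base_channels), call. = FALSE)
    }
  }
  structure(list(variant = variant, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 bins = as.integer(bins), window = as.integer(window),
                 spatial_mode = spatial_mode, hist_span = as.numeric(hist_span),
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes)),
            class = "model_spec")
}

spec_channels <- function(spec) spec$base_channels * 2^(seq_len(spec$depth) - 1)

is_hist_variant <- function(spec) spec$variant %in% c("joshua", "joshua_plus")
is_mult_variant <- function(spec) spec$variant %in% c("unet_plus", "joshua_plus")

spec_hist_config <- function(spec, level) {
  s <- spec_channels(spec)[level]
  histogram_config(s, spec$bins, s %/% spec$bins, spec$window,
                   spec$spatial_mode)
}

# uniform init with the conventional 1/sqrt(fan_in) bound
init_conv <- function(kh, kw, cin, cout) {
  bound <- 1 / sqrt(kh * kw * cin)
  list(w = array(runif(kh * kw * cin * cout, -bound, bound),
                 c(kh, kw, cin, cout)),
       b = runif(cout, -bound, bound))
}

#' Build a segmentation model from a spec
#'
#' Parameter initialisation is a pure function of `(spec, seed)`: two builds
#' with the same arguments give bit-identical parameter vectors.
#'
#' @param spec a [model_spec].
#' @param seed integer seed controlling initialisation.
#' @return an object of class `seg_model` with elements `spec`, `params`
#'   (flat named list of arrays) and attribute-free reproducibility.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  s <- spec_channels(spec)
  n <- spec$depth
  p <- list()
  add_dconv <- function(p, prefix, cin, cmid, cout) {
    c1 <- init_conv(3, 3, cin, cmid)
    c2 <- init_conv(3, 3, cmid, cout)
    p[[paste0(prefix, ".c1.w")]] <- c1$w; p[[paste0(prefix, ".c1.b")]] <- c1$b
    p[[paste0(prefix, ".c2.w")]] <- c2$w; p[[paste0(prefix, ".c2.b")]] <- c2$b
    p
  }
  # encoder
  p <- add_dconv(p, "inc", spec$in_channels, s[1], s[1])
  for (j in seq_len(n - 1)) p <- add_dconv(p, paste0("down", j), s[j], s[j + 1], s[j + 1])
  p <- add_dconv(p, paste0("down", n), s[n], s[n], s[n])   # bottleneck
  # skip transforms + decoder, deepest level first
  for (j in rev(seq_len(n))) {
    if (is_hist_variant(spec)) {
      k <- s[j] %/% spec$bins
      bound <- 1 / sqrt(s[j])
      p[[paste0("hist", j, ".w")]] <- matrix(runif(s[j] * k, -bound, bound), s[j], k)
      bp <- init_bin_params(spec$bins, k, spec$hist_span)
      p[[paste0("hist", j, ".mu")]] <- bp$centers
      p[[paste0("hist", j, ".gamma")]] <- bp$widths
    }
    if (spec$variant == "attention_unet") {
      fint <- max(1L, s[j] %/% 2L)
      wg <- init_conv(1, 1, s[j], fint)
      wx <- init_conv(1, 1, s[j], fint)
      psi <- init_conv(1, 1, fint, 1)
      p[[paste0("att", j, ".wg.w")]] <- wg$w; p[[paste0("att", j, ".wg.b")]] <- wg$b
      p[[paste0("att", j, ".wx.w")]] <- wx$w
      p[[paste0("att", j, ".psi.w")]] <- psi$w; p[[paste0("att", j, ".psi.b")]] <- psi$b
    }
    cin <- if (is_mult_variant(spec)) s[j] else 2L * s[j]
    cout <- if (j > 1) s[j] %/% 2L else s[1]
    p <- add_dconv(p, paste0("up", j), cin, s[j], cout)
  }
  oc <- init_conv(1, 1, s[1], spec$out_classes)
  p[["outc.w"]] <- oc$w; p[["outc.b"]] <- oc$b

  structure(list(spec = spec, params = p, seed = as.integer(seed)),
            class = "seg_model")
}

#' Number of learnable parameters
#'
#' Sum of the sizes of all trainable arrays, including histogram bin
#' centres/widths and 1x1 reducers for the joshua variants.
#'
#' @param model a `seg_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s  depth=%d base=%d  parameters=%s\n",
              x$spec$variant, x$spec$depth, x$spec$base_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Concatenation fusion of skip and decoder features
#'
#' Stacks the skip-connection map in front of the decoder map along the
#' channel axis (no values change), giving the following decoder block
#' `2 * D` input channels.
#'
#' @param a skip feature map `(H, W, D)`.
#' @param x_dec decoder feature map `(H, W, D)`.
#' @return array `(H, W, 2D)`.
#' @export
fuse_concat <- function(a, x_dec) {
  concat_channels(as_hwc(a), as_hwc(x_dec))
}

#' Attention-inspired multiplicative fusion
#'
#' Elementwise (Hadamard) product of the skip-connection map — for JOSHUA+
#' the histogram output, whose values in `(0, 1]` act as compatibility
#' scores — with the decoder map, enforcing joint agreement between encoder
#' and decoder features. Keeps D channels, halving the decoder input
#' relative to concatenation.
#'
#' @param h skip feature map `(H, W, D)`.
#' @param x_dec decoder feature map `(H, W, D)`.
#' @return array `(H, W, D)`.
#' @export
fuse_multiply <- function(h, x_dec) {
  h <- as_hwc(h); x_dec <- as_hwc(x_dec)
  if (!identical(dim(h), dim(x_dec))) {
    stop("multiplicative fusion requires identical shapes", call. = FALSE)
  }
  h * x_dec
}

# attention gate: additive attention on the skip connection ------------------

att_fwd <- function(e, u, p, j) {
  pre <- paste0("att", j)
  a <- conv_fwd(u, p[[paste0(pre, ".wg.w")]], p[[paste0(pre, ".wg.b")]], 0L)
  bx <- conv_fwd(e, p[[paste0(pre, ".wx.w")]],
                 numeric(dim(p[[paste0(pre, ".wx.w")]])[4]), 0L)
  z0 <- a + bx
  z <- relu_fwd(z0)
  ps <- conv_fwd(z, p[[paste0(pre, ".psi.w")]], p[[paste0(pre, ".psi.b")]], 0L)
  alpha <- sigmoid(ps)
  list(out = e * c(alpha), e = e, u = u, z0 = z0, z = z, alpha = alpha)
}

att_bwd <- function(cache, p, j, gout, grads) {
  pre <- paste0("att", j)
  d <- dim(cache$e)
  galpha <- array(rowSums(matrix(gout * cache$e, d[1] * d[2], d[3])),
                  c(d[1], d[2], 1))
  ge <- gout * c(cache$alpha)
  gps <- galpha * cache$alpha * (1 - cache$alpha)
  cps <- conv_bwd(cache$z, p[[paste0(pre, ".psi.w")]], gps, 0L)
  grads[[paste0(pre, ".psi.w")]] <- cps$gw
  grads[[paste0(pre, ".psi.b")]] <- cps$gb
  gz <- relu_bwd(cache$z0, cps$gx)
  cwg <- conv_bwd(cache$u, p[[paste0(pre, ".wg.w")]], gz, 0L)
  grads[[paste0(pre, ".wg.w")]] <- cwg$gw
  grads[[paste0(pre, ".wg.b")]] <- cwg$gb
  cwx <- conv_bwd(cache$e, p[[paste0(pre, ".wx.w")]], gz, 0L)
  grads[[paste0(pre, ".wx.w")]] <- cwx$gw
  grads[["..ge"]] <- ge + cwx$gx
  grads[["..gu"]] <- cwg$gx
  grads
}

#' Additive attention gate applied to an encoder feature map
#'
#' The gating mechanism of attention UNET: 1x1 projections of the encoder
#' map and the gating (decoder) signal are summed, passed through ReLU, a
#' 1x1 projection to a scalar and a sigmoid, and the resulting coefficients
#' in `(0, 1)` are multiplied onto the encoder map.
#'
#' @param x_enc encoder feature map `(H, W, D)`.
#' @param x_dec gating signal, same spatial size, D channels.
#' @param params named list `wg_w (1,1,D,F)`, `wg_b (F)`, `wx_w (1,1,D,F)`,
#'   `psi_w (1,1,F,1)`, `psi_b (1)`.
#' @return list with `out` (gated encoder map) and `coefficients`
#'   (`(H, W, 1)` array strictly inside `(0, 1)`).
#' @export
attention_gate <- function(x_enc, x_dec, params) {
  x_enc <- as_hwc(x_enc); x_dec <- as_hwc(x_dec)
  if (!all(dim(x_enc)[1:2] == dim(x_dec)[1:2])) {
    stop("attention gate requires matching spatial dims", call. = FALSE)
  }
  p <- list("att0.wg.w" = params$wg_w, "att0.wg.b" = params$wg_b,
            "att0.wx.w" = params$wx_w, "att0.psi.w" = params$psi_w,
            "att0.psi.b" = params$psi_b)
  f <- att_fwd(x_enc, x_dec, p, 0)
  list(out = f$out, coefficients = f$alpha)
}

# full network forward / backward -------------------------------------------

model_forward <- function(model, x, want_cache = FALSE) {
  spec <- model$spec; p <- model$params
  x <- as_hwc(x)
  d <- dim(x)
  n <- spec$depth
  div <- 2^n
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf(
      "resize required: input %dx%d not divisible by 2^depth = %d (inputs are never silently cropped)",
      d[1], d[2], div), call. = FALSE)
  }
  if (d[3] != spec$in_channels) {
    stop(sprintf("model expects %d input channels, got %d",
                 spec$in_channels, d[3]), call. = FALSE)
  }
  hist <- is_hist_variant(spec); mult <- is_mult_variant(spec)
  attn <- spec$variant == "attention_unet"

  ca <- list(enc = vector("list", n), pool = vector("list", n),
             dec = vector("list", n))
  h <- x
  for (j in seq_len(n)) {
    prefix <- if (j == 1) "inc" else paste0("down", j - 1)
    dc <- dconv_fwd(h, p, prefix)
    ca$enc[[j]] <- dc
    pl <- cpp_maxpool2_fwd(dc$out)
    ca$pool[[j]] <- list(idx = pl$idx, dims = dim(dc$out)[1:2])
    h <- pl$out
  }
  ca$bott <- dconv_fwd(h, p, paste0("down", n))
  dcur <- ca$bott$out
  for (j in rev(seq_len(n))) {
    ed <- dim(ca$enc[[j]]$out)
    lc <- list(u_in_dims = dim(dcur)[1:2])
    u <- cpp_bilinear_fwd(dcur, ed[1], ed[2])
    s <- ca$enc[[j]]$out
    if (hist) {
      cfg <- spec_hist_config(spec, j)
      hb <- hist_block_fwd(s, cfg, p[[paste0("hist", j, ".w")]],
                           p[[paste0("hist", j, ".mu")]],
                           p[[paste0("hist", j, ".gamma")]])
      lc$hist <- hb
      s <- hb$out
    }
    if (attn) {
      ag <- att_fwd(s, u, p, j)
      lc$att <- ag
      s <- ag$out
    }
    f <- if (mult) s * u else concat_channels(s, u)
    lc$s <- s; lc$u <- u
    lc$dc <- dconv_fwd(f, p, paste0("up", j))
    ca$dec[[j]] <- lc
    dcur <- lc$dc$out
  }
  logits <- conv_fwd(dcur, p[["outc.w"]], p[["outc.b"]], 0L)
  list(prob = sigmoid(logits), logits = logits,
       cache = if (want_cache) c(ca, list(dtop = dcur, x = x)) else NULL)
}

model_backward <- function(model, cache, glogits) {
  spec <- model$spec; p <- model$params
  n <- spec$depth
  hist <- is_hist_variant(spec); mult <- is_mult_variant(spec)
  attn <- spec$variant == "attention_unet"

  grads <- list()
  co <- conv_bwd(cache$dtop, p[["outc.w"]], glogits, 0L)
  grads[["outc.w"]] <- co$gw; grads[["outc.b"]] <- co$gb
  g <- co$gx

  gskip <- vector("list", n)
  for (j in seq_len(n)) {           # top decoder level first
    lc <- cache$dec[[j]]
    grads <- dconv_bwd(lc$dc, p, paste0("up", j), g, grads)
    gf <- grads[["..gx"]]
    if (mult) {
      gs <- gf * lc$u
      gu <- gf * lc$s
    } else {
      sp <- split_channels(gf, dim(lc$s)[3])
      gs <- sp[[1]]; gu <- sp[[2]]
    }
    if (attn) {
      grads <- att_bwd(lc$att, p, j, gs, grads)
      gs <- grads[["..ge"]]
      gu <- gu + grads[["..gu"]]
    }
    if (hist) {
      cfg <- spec_hist_config(spec, j)
      hb <- hist_block_bwd(cache$enc[[j]]$out, cfg,
                           p[[paste0("hist", j, ".w")]],
                           p[[paste0("hist", j, ".mu")]],
                           p[[paste0("hist", j, ".gamma")]],
                           lc$hist, gs)
      grads[[paste0("hist", j, ".w")]] <- hb$gw
      grads[[paste0("hist", j, ".mu")]] <- hb$gmu
      grads[[paste0("hist", j, ".gamma")]] <- hb$ggamma
      gs <- hb$gx
    }
    gskip[[j]] <- gs
    g <- cpp_bilinear_bwd(gu, lc$u_in_dims[1], lc$u_in_dims[2])
  }
  grads <- dconv_bwd(cache$bott, p, paste0("down", n), g, grads)
  g <- grads[["..gx"]]
  for (j in rev(seq_len(n))) {
    pl <- cache$pool[[j]]
    gup <- cpp_maxpool2_bwd(pl$idx, g, pl$dims[1], pl$dims[2])
    gtotal <- gup + gskip[[j]]
    prefix <- if (j == 1) "inc" else paste0("down", j - 1)
    grads <- dconv_bwd(cache$enc[[j]], p, prefix, gtotal, grads)
    g <- grads[["..gx"]]
  }
  grads[["..gx"]] <- NULL
  grads[["..ge"]] <- NULL
  grads[["..gu"]] <- NULL
  grads
}

#' Predict a binary mask for an image
#'
#' Runs the forward pass and thresholds the sigmoid probability map; ties
#' (`prob == threshold`) are assigned to the positive class.
#'
#' @param model a `seg_model`.
#' @param image array `(H, W, 3)` with values in `[0, 1]`; H and W must be
#'   divisible by `2^depth` (resize first, the model never crops silently).
#' @param threshold decision threshold, default 0.5.
#' @param return_prob also return the probability map.
#' @return integer `(H, W)` matrix of 0/1, or a list with `mask` and `prob`
#'   when `return_prob = TRUE`.
#' @export
predict_mask <- function(model, image, threshold = 0.5, return_prob = FALSE) {
  fw <- model_forward(model, image)
  prob <- fw$prob[, , 1]
  mask <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  if (return_prob) list(mask = mask, prob = prob) else mask
}

# checkpoints ---------------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint is a single archive holding the spec and all parameter
#' arrays. Loading revalidates the spec invariants and checks that every
#' parameter has the shape a fresh build would produce.
#'
#' @param model a `seg_model`.
#' @param path file path for the checkpoint archive.
#' @return `load_checkpoint` returns the restored `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(spec = unclass(model$spec), params = model$params,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- do.call(model_spec, ck$spec)   # revalidates invariants
  ref <- build_model(spec, seed = if (is.null(ck$seed)) 0L else ck$seed)
  if (!identical(names(ref$params), names(ck$params))) {
    stop("checkpoint parameters do not match the spec's architecture",
         call. = FALSE)
  }
  for (nm in names(ref$params)) {
    if (!identical(dim(ref$params[[nm]]), dim(ck$params[[nm]])) ||
        length(ref$params[[nm]]) != length(ck$params[[nm]])) {
      stop(sprintf("checkpoint parameter `%s` has an unexpected shape", nm),
           call. = FALSE)
    }
  }
  ref$params <- ck$params
  ref
}
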