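#' Learnable histogram bin parameters
#'
#' Bin centres \eqn{\mu_{bk}} and widths \eqn{\gamma_{bk}} of a spatial
#' histogram layer, one pair per (bin, reduced channel). The width enters the
#' radial-basis response only as \eqn{\gamma^2}, so the layer's output is
#' invariant to the sign of any width entry.
#'
#' @param centers numeric matrix `(bins, channels)` of bin centres.
#' @param widths numeric matrix of the same shape, inverse-feature-scale.
#' @return an object of class `bin_params`.
#' @export
bin_params <- function(centers, widths) {
  centers <- as.matrix(centers)
  widths <- as.matrix(widths)
  assert_finite(centers)
  assert_finite(widths)
  if (!identical(dim(centers), dim(widths))) {
    stop("`centers` and `widths` must have identical (bins, channels) shape",
         call. = FALSE)
  }
  structure(list(centers = centers, widths = widths), class = "bin_params")
}

#' Default initial bin parameters
#'
#' Centres are linearly spaced on `span` (the same grid for every reduced
#' channel); widths start at the constant `bins / 4` so that adjacent
#' radial-basis bins overlap moderately. Both are learnable.
#'
#' @param bins number of bins B.
#' @param channels number of reduced channels K.
#' @param span numeric length-2, feature-space interval covered by the centres.
#' @return a [bin_params] object.
#' @export
init_bin_params <- function(bins, channels, span = c(-2, 2)) {
  centers <- matrix(seq(span[1], span[2], length.out = bins), bins, channels)
  widths <- matrix(bins / 4, bins, channels)
  bin_params(centers, widths)
}

#' Configuration of a histogram block
#'
#' A histogram block reduces its D input channels to K with a learned 1x1
#' projection and soft-bins each reduced channel into B local histograms, so
#' its output again has `B * K == D` channels (channel conservation: the
#' block can replace a plain skip connection without changing any decoder
#' shape).
#'
#' @param input_channels D, channels of the incoming encoder feature map.
#' @param bins B, number of histogram bins per reduced channel.
#' @param reduced_channels K; must satisfy `B * K == D`.
#' @param window integer length-2 `(S, T)` local window of the histogram.
#' @param spatial_mode `"preserve"` (stride-1 sliding window with replicate
#'   edge clamping; output size equals input size) or `"pool"`
#'   (non-overlapping windows followed by bilinear upsampling back).
#' @return an object of class `histogram_config`.
#' @export
histogram_config <- function(input_channels, bins,
                             reduced_channels = input_channels %/% bins,
                             window = c(2, 2),
                             spatial_mode = c("preserve", "pool")) {
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(input_channels >= 1, bins >= 1, reduced_channels >= 1,
            length(window) == 2, all(window >= 1))
  if (bins * reduced_channels != input_channels) {
    stop(sprintf(
      "channel conservation violated: bins (%d) x reduced_channels (%d) != input_channels (%d)",
      bins, reduced_channels, input_channels), call. = FALSE)
  }
  structure(list(input_channels = as.integer(input_channels),
                 bins = as.integer(bins),
                 reduced_channels = as.integer(reduced_channels),
                 window = as.integer(window),
                 spatial_mode = spatial_mode),
            class = "histogram_config")
}

#' Radial-basis bin response
#'
#' The scalar summand of the histogram layer:
#' `exp(-gamma^2 * (x - mu)^2)`. Equals 1 exactly when `x == mu` or
#' `gamma == 0`, decreases strictly in `|x - mu|` otherwise, and is
#' symmetric both in `x - mu` and in the sign of `gamma`.
#'
#' @param x feature value(s).
#' @param mu bin centre.
#' @param gamma bin width parameter (enters squared).
#' @return response in `(0, 1]`, same shape as `x`.
#' @export
rbf_bin_response <- function(x, mu, gamma) {
  assert_finite(x); assert_finite(mu); assert_finite(gamma)
  exp(-(gamma^2) * (x - mu)^2)
}

#' 1x1 channel reduction
#'
#' Per-pixel linear projection from D to K channels (no bias, no
#' nonlinearity): the dimension-reduction step in front of the histogram
#' binning.
#'
#' @param x feature map array `(H, W, D)`.
#' @param weights numeric `D x K` projection matrix.
#' @return array `(H, W, K)`.
#' @export
reduce_channels <- function(x, weights) {
  x <- as_hwc(x)
  weights <- as.matrix(weights)
  d <- dim(x)
  if (nrow(weights) != d[3]) {
    stop(sprintf("projection expects %d input channels, feature map has %d",
                 nrow(weights), d[3]), call. = FALSE)
  }
  out <- matrix(x, d[1] * d[2], d[3]) %*% weights
  array(out, c(d[1], d[2], ncol(weights)))
}

#' Local spatial histogram
#'
#' Soft-bins every channel of `x` into B local histograms: each output entry
#' is the `1/(S*T)` window average of [rbf_bin_response] over the S x T
#' neighbourhood. Output channels are bin-major within each source channel
#' (channel k's B bin maps occupy slices `(k-1)*B + 1 .. k*B`).
#'
#' @param x feature map array `(H, W, K)`.
#' @param bins a [bin_params] with shape `(B, K)`.
#' @param window integer `(S, T)` window.
#' @param spatial_mode `"preserve"` or `"pool"` (see [histogram_config]).
#' @return array `(H, W, B*K)` with values in `(0, 1]`.
#' @export
local_histogram <- function(x, bins, window = c(2, 2),
                            spatial_mode = c("preserve", "pool")) {
  spatial_mode <- match.arg(spatial_mode)
  x <- as_hwc(x)
  assert_finite(x)
  if (!inherits(bins, "bin_params")) stop("`bins` must be a bin_params object")
  d <- dim(x)
  if (ncol(bins$centers) != d[3]) {
    stop(sprintf("bin params describe %d channels, feature map has %d",
                 ncol(bins$centers), d[3]), call. = FALSE)
  }
  if (window[1] > d[1] || window[2] > d[2]) {
    stop("histogram window larger than the feature map", call. = FALSE)
  }
  h <- cpp_hist_fwd(x, bins$centers, bins$widths,
                    as.integer(window[1]), as.integer(window[2]),
                    spatial_mode == "preserve")
  if (spatial_mode == "pool") h <- cpp_bilinear_fwd(h, d[1], d[2])
  h
}

#' Histogram block: 1x1 reduction followed by local histogram
#'
#' The drop-in skip-connection block: D encoder channels are projected to K
#' channels and soft-binned into B local histograms, giving `B*K == D`
#' output channels at the input's spatial size, ready to be concatenated
#' with (JOSHUA) or multiplied into (JOSHUA+) the same-level decoder map.
#'
#' @param x encoder feature map `(H, W, D)`.
#' @param config a [histogram_config] with `input_channels == D`.
#' @param params list with `weights` (`D x K`), and `bins` (a [bin_params]).
#' @return array `(H, W, D)` with values in `(0, 1]`.
#' @export
histogram_block <- function(x, config, params) {
  x <- as_hwc(x)
  d <- dim(x)
  if (d[3] != config$input_channels) {
    stop(sprintf("histogram block built for %d channels, input has %d",
                 config$input_channels, d[3]), call. = FALSE)
  }
  r <- reduce_channels(x, params$weights)
  local_histogram(r, params$bins, config$window, config$spatial_mode)
}

# internal: histogram block forward with cache, and backward -----------------

hist_block_fwd <- function(x, config, weights, mu, gamma) {
  r <- reduce_channels(x, weights)
  stride1 <- config$spatial_mode == "preserve"
  h <- cpp_hist_fwd(r, mu, gamma, config$window[1], config$window[2], stride1)
  if (!stride1) {
    hp <- h
    h <- cpp_bilinear_fwd(h, dim(x)[1], dim(x)[2])
    list(out = h, r = r, pool_dims = dim(hp)[1:2])
  } else {
    list(out = h, r = r, pool_dims = NULL)
  }
}

hist_block_bwd <- function(x, config, weights, mu, gamma, cache, gout) {
  stride1 <- config$spatial_mode == "preserve"
  if (!stride1) {
    gout <- cpp_bilinear_bwd(gout, cache$pool_dims[1], cache$pool_dims[2])
  }
  g <- cpp_hist_bwd(cache$r, mu, gamma, config$window[1], config$window[2],
                    stride1, gout)
  d <- dim(x)
  gr <- matrix(g$gx, d[1] * d[2], dim(cache$r)[3])
  xm <- matrix(x, d[1] * d[2], d[3])
  gw <- crossprod(xm, gr)                      # D x K
  gx <- array(gr %*% t(weights), d)
  list(gx = gx, gw = gw, gmu = g$gmu, ggamma = g$ggam)
}
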