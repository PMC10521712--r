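# Image/mask I/O, resizing, augmentation and cross-validation fold schemes.

read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read `%s`: no such file", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      im <- EBImage::readImage(path)
      a <- EBImage::imageData(im)
      if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop(sprintf("unsupported image format `%s`", ext), call. = FALSE))
  x
}

to_rgb <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(x)[3] == 1) x <- array(rep(x, 3), c(dim(x)[1:2], 3))
  x
}

#' Construct a histology image object
#'
#' @param pixels RGB array `(H, W, 3)` with values in `[0, 1]`.
#' @param id image identifier.
#' @param week,condition,stain,reference_length optional metadata: time
#'   point in weeks (1/2/4/8), biomaterial condition, stain (`"HE"` or
#'   `"trichrome"`), and microscope reference length in micrometres per
#'   pixel.
#' @return an object of class `hist_image`.
#' @export
hist_image <- function(pixels, id = "img", week = NA, condition = NA_character_,
                       stain = NA_character_, reference_length = NA_real_) {
  pixels <- to_rgb(as_hwc(pixels))
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pixels = pixels, id = id, week = week, condition = condition,
                 stain = stain, reference_length = reference_length),
            class = "hist_image")
}

#' Load an image/mask pair from disk
#'
#' Reads a PNG/TIFF/JPEG image and a single-channel mask with values
#' `{0, 255}` or `{0, 1}`; the mask is binarised (nonzero -> 1). Shapes
#' must agree and intermediate mask values are rejected.
#'
#' @param image_path,mask_path file paths.
#' @param ... metadata passed to [hist_image].
#' @return list with `image` (a [hist_image]) and `mask` (0/1 integer
#'   matrix).
#' @export
load_pair <- function(image_path, mask_path, ...) {
  img <- to_rgb(read_raster(image_path))
  m <- read_raster(mask_path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  v <- round(m * 255)
  if (!all(v %in% c(0, 255)) && !all(v %in% c(0, 1))) {
    stop(sprintf("mask `%s` is not binary after collapsing (values beyond {0,1}/{0,255})",
                 mask_path), call. = FALSE)
  }
  mask <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  if (!all(dim(img)[1:2] == dim(mask))) {
    stop(sprintf("image (%dx%d) and mask (%dx%d) shapes disagree",
                 dim(img)[1], dim(img)[2], nrow(mask), ncol(mask)),
         call. = FALSE)
  }
  list(image = hist_image(img, id = tools::file_path_sans_ext(basename(image_path)), ...),
       mask = mask)
}

eb_resize <- function(x, h, w, nearest = FALSE) {
  # EBImage stores images x-major (width first); our arrays are (H, W, C)
  a <- if (length(dim(x)) == 3) aperm(x, c(2, 1, 3)) else t(x)
  im <- EBImage::Image(a, colormode = if (length(dim(x)) == 3) "Color" else "Grayscale")
  out <- EBImage::resize(im, w = w, h = h,
                         filter = if (nearest) "none" else "bilinear")
  a2 <- EBImage::imageData(out)
  if (length(dim(a2)) == 3) aperm(a2, c(2, 1, 3)) else t(a2)
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation; the mask with
#' nearest-neighbour (binary labels must stay binary) and re-binarised.
#' The original dimensions are recorded for later physical-area
#' back-scaling.
#'
#' @param image a [hist_image] or `(H, W, 3)` array.
#' @param mask 0/1 matrix or `NULL`.
#' @param target integer `(height, width)`, default `c(256, 256)`.
#' @param depth encoder depth the result should feed; a warning is issued
#'   if the target is not divisible by `2^depth`.
#' @return list `image`, `mask`, `original_dims`.
#' @export
resize_pair <- function(image, mask = NULL, target = c(256, 256), depth = 4) {
  was_hist <- inherits(image, "hist_image")
  px <- if (was_hist) image$pixels else to_rgb(as_hwc(image))
  orig <- dim(px)[1:2]
  if (any(target %% 2^depth != 0)) {
    warning(sprintf("target %dx%d is not divisible by 2^depth = %d; the model will reject it",
                    target[1], target[2], 2^depth))
  }
  out_px <- pmin(pmax(eb_resize(px, target[1], target[2]), 0), 1)
  out_mask <- NULL
  if (!is.null(mask)) {
    assert_binary_mask(mask)
    out_mask <- matrix(as.integer(eb_resize(mask + 0, target[1], target[2],
                                            nearest = TRUE) != 0),
                       target[1], target[2])
  }
  if (was_hist) {
    image$pixels <- out_px
    out_img <- image
  } else {
    out_img <- out_px
  }
  list(image = out_img, mask = out_mask, original_dims = orig)
}

# geometric transforms (applied identically to image and mask) ---------------

hflip_hwc <- function(x) {
  if (is.matrix(x)) x[, ncol(x):1] else x[, dim(x)[2]:1, , drop = FALSE]
}

rot90_hwc <- function(x, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) {
    x <- if (is.matrix(x)) t(x)[nrow(t(x)):1, ] else {
      y <- aperm(x, c(2, 1, 3))
      y[dim(y)[1]:1, , , drop = FALSE]
    }
  }
  x
}

# numeric hsv -> rgb (grDevices::hsv returns strings, too slow per pixel)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Random training augmentation
#'
#' The training-time recipe: horizontal flip with probability 0.5, rotation
#' drawn uniformly from 90-degree increments (0/90/180/270), colour jitter
#' on the image only (brightness, contrast and saturation each applied with
#' probability 0.5 with factors in `1 +/- jitter`; hue with probability
#' 0.05, shifted by at most `hue`), and an optional random crop. Geometric
#' transforms are applied identically to image and mask, so positive-pixel
#' counts are preserved. Deterministic given the R random seed.
#'
#' @param image `(H, W, 3)` array in `[0, 1]` (or [hist_image]).
#' @param mask 0/1 matrix.
#' @param brightness,contrast,saturation jitter half-ranges (default 0.25).
#' @param hue maximal hue shift (default 0.05).
#' @param crop_size optional integer `(h, w)` random crop (e.g. 416x416 for
#'   large-tile training); must not exceed the image.
#' @return list `image`, `mask`.
#' @export
augment <- function(image, mask, brightness = 0.25, contrast = 0.25,
                    saturation = 0.25, hue = 0.05, crop_size = NULL) {
  px <- if (inherits(image, "hist_image")) image$pixels else to_rgb(as_hwc(image))
  if (runif(1) < 0.5) {
    px <- hflip_hwc(px); mask <- hflip_hwc(mask)
  }
  k <- sample(0:3, 1)
  if (k > 0) {
    px <- rot90_hwc(px, k); mask <- rot90_hwc(mask, k)
  }
  if (runif(1) < 0.5) px <- clip01(px * runif(1, 1 - brightness, 1 + brightness))
  if (runif(1) < 0.5) {
    f <- runif(1, 1 - contrast, 1 + contrast)
    gm <- mean(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    px <- clip01(f * px + (1 - f) * gm)
  }
  if (runif(1) < 0.5) {
    f <- runif(1, 1 - saturation, 1 + saturation)
    gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    px <- clip01(f * px + (1 - f) * array(rep(gray, 3), dim(px)))
  }
  if (runif(1) < 0.05) {
    shift <- runif(1, -hue, hue)
    d <- dim(px)
    hsv <- grDevices::rgb2hsv(t(matrix(px, d[1] * d[2], 3)), maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1, ] + shift, hsv[2, ], hsv[3, ])
    px <- clip01(array(rgb, d))
  }
  if (!is.null(crop_size)) {
    d <- dim(px)
    if (crop_size[1] > d[1] || crop_size[2] > d[2]) {
      stop("crop larger than the image", call. = FALSE)
    }
    r0 <- sample(d[1] - crop_size[1] + 1, 1)
    c0 <- sample(d[2] - crop_size[2] + 1, 1)
    px <- px[r0:(r0 + crop_size[1] - 1), c0:(c0 + crop_size[2] - 1), , drop = FALSE]
    mask <- mask[r0:(r0 + crop_size[1] - 1), c0:(c0 + crop_size[2] - 1)]
  }
  list(image = px, mask = mask)
}

# fold assignment schemes ----------------------------------------------------

#' Assign images to cross-validation folds
#'
#' Five schemes:
#' * `random_kfold` — random partition into k folds ignoring labels.
#' * `stratified_time` / `stratified_condition` — k folds keeping per-fold
#'   label proportions within one image per label of the global
#'   proportions (round-robin over shuffled label groups).
#' * `fold_by_week` — one fold per distinct week; validating on fold w
#'   means validating on exactly week-w images (k is forced to the number
#'   of weeks).
#' * `validate_week8` — all week-8 images form the validation set (fold 1);
#'   all other images are training (fold 0).
#'
#' @param ids character vector of image ids.
#' @param labels label per id: weeks for `stratified_time`, `fold_by_week`
#'   and `validate_week8`; conditions for `stratified_condition`. Ignored
#'   for `random_kfold`.
#' @param scheme one of the five scheme names.
#' @param k number of folds (k-fold schemes; default 5).
#' @param seed RNG seed; identical seed gives an identical assignment.
#' @return an object of class `fold_assignment`: data frame `(id, fold)`
#'   with attributes `scheme`, `k`, `seed`.
#' @export
make_folds <- function(ids, labels = NULL,
                       scheme = c("random_kfold", "stratified_time",
                                  "stratified_condition", "fold_by_week",
                                  "validate_week8"),
                       k = 5, seed = 0L) {
  scheme <- match.arg(scheme)
  stopifnot(length(ids) >= 1, !anyDuplicated(ids))
  needs_labels <- scheme != "random_kfold"
  if (needs_labels && (is.null(labels) || length(labels) != length(ids))) {
    stop(sprintf("scheme `%s` requires one label per id", scheme), call. = FALSE)
  }
  if (scheme %in% c("random_kfold", "stratified_time", "stratified_condition") &&
      k < 2) {
    stop("k-fold schemes require k >= 2", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  fold <- integer(length(ids))
  if (scheme == "random_kfold") {
    ord <- sample(length(ids))
    fold[ord] <- rep_len(seq_len(k), length(ids))
  } else if (scheme %in% c("stratified_time", "stratified_condition")) {
    nxt <- 0L
    for (lv in sort(unique(as.character(labels)))) {
      members <- which(as.character(labels) == lv)
      members <- members[sample(length(members))]
      fold[members] <- (nxt + seq_along(members) - 1L) %% k + 1L
      nxt <- (nxt + length(members)) %% k
    }
  } else if (scheme == "fold_by_week") {
    weeks <- sort(unique(as.numeric(labels)))
    k <- length(weeks)
    fold <- match(as.numeric(labels), weeks)
  } else {  # validate_week8
    fold <- as.integer(as.numeric(labels) == 8)
    k <- 1L
    if (!any(fold == 1)) stop("no week-8 images to validate on", call. = FALSE)
  }
  structure(data.frame(id = ids, fold = fold, stringsAsFactors = FALSE),
            scheme = scheme, k = as.integer(k), seed = as.integer(seed),
            class = c("fold_assignment", "data.frame"))
}

#' Train/validation split for one fold
#'
#' @param folds a [make_folds] result.
#' @param fold validation fold index (for `validate_week8` the only choice
#'   is 1).
#' @return list `train` and `val` of image ids.
#' @export
fold_split <- function(folds, fold = 1) {
  stopifnot(inherits(folds, "fold_assignment"))
  val <- folds$id[folds$fold == fold]
  if (!length(val)) stop(sprintf("fold %s has no validation images", fold),
                         call. = FALSE)
  list(train = folds$id[folds$fold != fold], val = val)
}
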