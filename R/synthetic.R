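# Synthetic histology-like image generator. Emulates the appearance that
# matters for adipose segmentation: white elliptical adipocyte regions with
# a thin darker membrane ring on a smoothly varying pink/purple (H&E) or
# blue/red (trichrome) textured background, with paired pixel-exact masks
# and a controllable adipose fraction, including the adipose-poor regime
# (< 1% positive pixels).

stain_palette <- list(
  HE = list(base = c(0.91, 0.76, 0.82),     # eosin pink
            accent = c(0.58, 0.42, 0.66),   # hematoxylin purple
            membrane = c(0.72, 0.42, 0.52),
            interior = c(0.975, 0.965, 0.97)),
  trichrome = list(base = c(0.62, 0.71, 0.86),   # collagen blue
                   accent = c(0.78, 0.35, 0.38), # keratin/muscle red
                   membrane = c(0.55, 0.30, 0.45),
                   interior = c(0.975, 0.965, 0.97))
)

#' Specification of a synthetic histology dataset
#'
#' Generation is a pure function of this spec: the same spec (including
#' `seed`) produces byte-identical images, masks and manifest.
#'
#' @param n_images number of image/mask pairs.
#' @param height,width image size in pixels.
#' @param adipose_fraction_range interval `[lo, hi]` in `[0, 1]` the
#'   realised positive-pixel fraction must fall in (rejection-resampled);
#'   use e.g. `c(0, 0.01)` for the adipose-poor regime.
#' @param n_blobs_range integer interval for the number of adipocytes.
#' @param blob_axis_range interval for ellipse semi-axes, pixels.
#' @param membrane_width membrane ring thickness, pixels.
#' @param stain `"HE"` or `"trichrome"`.
#' @param noise_sd standard deviation of fine pixel noise.
#' @param reference_length microscope calibration written to the manifest,
#'   micrometres per pixel.
#' @param seed RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images = 32, height = 64, width = 64,
                           adipose_fraction_range = c(0.02, 0.35),
                           n_blobs_range = c(2, 10),
                           blob_axis_range = c(3, 9),
                           membrane_width = 1.5,
                           stain = c("HE", "trichrome"),
                           noise_sd = 0.02,
                           reference_length = 2.0,
                           seed = 0L) {
  stain <- match.arg(stain)
  stopifnot(n_images >= 1, height >= 8, width >= 8,
            length(adipose_fraction_range) == 2,
            adipose_fraction_range[1] <= adipose_fraction_range[2],
            adipose_fraction_range[1] >= 0, adipose_fraction_range[2] <= 1,
            n_blobs_range[1] <= n_blobs_range[2], n_blobs_range[1] >= 0,
            blob_axis_range[1] <= blob_axis_range[2], blob_axis_range[1] > 0,
            membrane_width >= 0, noise_sd >= 0, reference_length > 0)
  structure(list(n_images = as.integer(n_images),
                 height = as.integer(height), width = as.integer(width),
                 adipose_fraction_range = as.numeric(adipose_fraction_range),
                 n_blobs_range = as.integer(n_blobs_range),
                 blob_axis_range = as.numeric(blob_axis_range),
                 membrane_width = as.numeric(membrane_width),
                 stain = stain, noise_sd = as.numeric(noise_sd),
                 reference_length = as.numeric(reference_length),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# smooth low-frequency colour field via coarse noise + bilinear upsampling
lowfreq_field <- function(h, w, cells = 6, sd = 1) {
  g <- array(rnorm(cells * cells, sd = sd), c(cells, cells, 1))
  cpp_bilinear_fwd(g, h, w)[, , 1]
}

# ellipse rasteriser: squared radial coordinate of every pixel in a grid
ellipse_r2 <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

generate_one <- function(spec) {
  pal <- stain_palette[[spec$stain]]
  h <- spec$height; w <- spec$width
  lo <- spec$adipose_fraction_range[1]; hi <- spec$adipose_fraction_range[2]
  for (try in seq_len(60)) {
    n_blobs <- if (spec$n_blobs_range[2] == 0) 0L else
      sample(spec$n_blobs_range[1]:spec$n_blobs_range[2], 1)
    blobs <- list()
    for (bi in seq_len(n_blobs)) {
      placed <- FALSE
      for (attempt in seq_len(80)) {
        a <- runif(1, spec$blob_axis_range[1], spec$blob_axis_range[2])
        b <- runif(1, spec$blob_axis_range[1], spec$blob_axis_range[2])
        theta <- runif(1, 0, pi)
        rmax <- max(a, b) + spec$membrane_width
        if (rmax + 1 >= h - rmax || rmax + 1 >= w - rmax) next  # blob too big
        cy <- runif(1, rmax + 1, h - rmax)
        cx <- runif(1, rmax + 1, w - rmax)
        ok <- TRUE
        for (bl in blobs) {
          if (sqrt((cy - bl$cy)^2 + (cx - bl$cx)^2) <
              rmax + max(bl$a, bl$b) + spec$membrane_width + 1) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          blobs[[length(blobs) + 1]] <-
            list(cy = cy, cx = cx, a = a, b = b, theta = theta)
          placed <- TRUE
          break
        }
      }
      if (!placed) break   # image too crowded; fraction check decides
    }
    mask <- matrix(0L, h, w)
    membrane <- matrix(FALSE, h, w)
    for (bl in blobs) {
      r2 <- ellipse_r2(seq_len(h), seq_len(w), bl$cy, bl$cx, bl$a, bl$b,
                       bl$theta)
      r2m <- ellipse_r2(seq_len(h), seq_len(w), bl$cy, bl$cx,
                        bl$a + spec$membrane_width,
                        bl$b + spec$membrane_width, bl$theta)
      mask[r2 <= 1] <- 1L
      membrane <- membrane | (r2 > 1 & r2m <= 1)
    }
    frac <- mean(mask)
    if (frac >= lo && frac <= hi) {
      # background: base colour, accent patches, fine noise
      field <- lowfreq_field(h, w, cells = 6, sd = 1)
      weight <- clip01(0.72 + 0.25 * field)   # base stain dominates accent
      img <- array(0, c(h, w, 3))
      for (ch in 1:3) {
        img[, , ch] <- weight * pal$base[ch] + (1 - weight) * pal$accent[ch]
      }
      img <- img + array(rnorm(h * w * 3, sd = spec$noise_sd), c(h, w, 3))
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[membrane] <- pal$membrane[ch] + rnorm(sum(membrane), sd = spec$noise_sd)
        inside <- mask == 1
        sl[inside] <- pal$interior[ch] + rnorm(sum(inside), sd = spec$noise_sd / 2)
        img[, , ch] <- sl
      }
      return(list(image = clip01(img), mask = mask, fraction = frac,
                  blobs = blobs))
    }
  }
  stop(sprintf(
    paste0("synthetic generation failed: could not realise an adipose ",
           "fraction in [%.3f, %.3f] with %d-%d blobs of axes %.1f-%.1f px ",
           "on a %dx%d image after 60 attempts"),
    lo, hi, spec$n_blobs_range[1], spec$n_blobs_range[2],
    spec$blob_axis_range[1], spec$blob_axis_range[2], h, w), call. = FALSE)
}

synthetic_weeks <- c(1, 2, 4, 8)
synthetic_conditions <- c("silk", "silk-collagen", "silk-heparin", "silk+VEGF")

#' Generate a synthetic dataset in memory
#'
#' @param spec a [synthetic_spec].
#' @return list of pairs; each has `image` (`(H, W, 3)` array), `mask`
#'   (0/1 matrix), `id`, `week`, `condition`, `stain`, `reference_length`,
#'   `fraction` (realised adipose fraction) and `blobs` (the generating
#'   ellipse geometry: centre, semi-axes, rotation — usable as an
#'   independent geometric ground truth).
#' @export
generate_synthetic_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_images), function(i) {
    g <- generate_one(spec)
    c(g, list(id = sprintf("synth_%03d", i),
              week = synthetic_weeks[(i - 1) %% 4 + 1],
              condition = synthetic_conditions[((i - 1) %/% 4) %% 4 + 1],
              stain = spec$stain,
              reference_length = spec$reference_length))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/<id>.png`, `masks/<id>.png` (single-channel, 0/255) and a
#' `manifest.csv` with columns id, image_path, mask_path, week, condition,
#' stain, reference_length_um_per_px, original_height, original_width,
#' adipose_fraction. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame (invisibly also written to disk).
#' @export
generate_synthetic_dataset <- function(spec, out_dir) {
  pairs <- generate_synthetic_images(spec)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(pairs, function(p) {
    ip <- file.path(out_dir, "images", paste0(p$id, ".png"))
    mp <- file.path(out_dir, "masks", paste0(p$id, ".png"))
    png::writePNG(p$image, ip)
    png::writePNG(p$mask + 0, mp)
    data.frame(id = p$id, image_path = ip, mask_path = mp, week = p$week,
               condition = p$condition, stain = p$stain,
               reference_length_um_per_px = p$reference_length,
               original_height = nrow(p$mask), original_width = ncol(p$mask),
               adipose_fraction = p$fraction, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Load a dataset described by a manifest CSV
#'
#' @param manifest path to a manifest CSV (or an already-read data frame)
#'   with at least `id`, `image_path` and optionally `mask_path`, metadata
#'   columns as written by [generate_synthetic_dataset].
#' @return list of pairs as in [generate_synthetic_images] (mask `NULL`
#'   where absent).
#' @export
load_manifest <- function(manifest) {
  m <- if (is.character(manifest)) read.csv(manifest, stringsAsFactors = FALSE) else manifest
  base <- if (is.character(manifest)) dirname(manifest) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(m)), function(i) {
    has_mask <- "mask_path" %in% names(m) && nzchar(m$mask_path[i]) &&
      !is.na(m$mask_path[i])
    pr <- load_pair(resolve(m$image_path[i]),
                    if (has_mask) resolve(m$mask_path[i]) else resolve(m$image_path[i]))
    list(image = pr$image$pixels,
         mask = if (has_mask) pr$mask else NULL,
         id = m$id[i],
         week = if ("week" %in% names(m)) m$week[i] else NA,
         condition = if ("condition" %in% names(m)) m$condition[i] else NA,
         stain = if ("stain" %in% names(m)) m$stain[i] else NA,
         reference_length = if ("reference_length_um_per_px" %in% names(m))
           m$reference_length_um_per_px[i] else NA_real_)
  })
}
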