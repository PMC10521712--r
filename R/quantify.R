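# Physical adipose-area quantification and the end-to-end segment/quantify
# workflow.

#' Physical adipose area from a predicted mask
#'
#' Maps the positive-pixel count of a (typically downsampled) mask back to
#' physical area: `fa_full = fa_down * (ia_full / ia_down) * rl^2` where
#' `fa_down` is the positive-pixel count, `ia_down` the mask's pixel area,
#' `ia_full` the full-resolution image's pixel area, and `rl` the
#' microscope reference length in micrometres per pixel. Doubling `rl`
#' quadruples the area; scaling `ia_full` by c scales it by c.
#'
#' @param mask 0/1 mask matrix (downsampled resolution).
#' @param ia_full full-resolution image pixel area (e.g. `H0 * W0`).
#' @param rl reference length, micrometres per pixel; must be present and
#'   positive — there is no silent default calibration.
#' @return object of class `area_measurement`: `fa_down`, `ia_down`,
#'   `ia_full`, `rl`, `fa_full` (square micrometres).
#' @export
adipose_area <- function(mask, ia_full, rl) {
  if (missing(rl) || is.null(rl) || is.na(rl)) {
    stop("missing calibration: a reference length (um/px) is required",
         call. = FALSE)
  }
  if (rl <= 0) stop("reference length must be positive", call. = FALSE)
  assert_binary_mask(mask)
  fa_down <- sum(mask == 1)
  ia_down <- length(mask)
  structure(list(fa_down = fa_down, ia_down = ia_down,
                 ia_full = ia_full, rl = rl,
                 fa_full = fa_down * (ia_full / ia_down) * rl^2),
            class = "area_measurement")
}

#' Aggregate area measurements by group
#'
#' Median and 25th/75th percentile quartiles (linear interpolation,
#' quantile type 7) of the physical adipose area per group, with groups
#' sorted numerically (weeks) or lexically (conditions). Stable under
#' permutation of the input rows.
#'
#' @param areas data frame with a `fa_full_um2` column and the grouping
#'   column.
#' @param by grouping column name, `"week"` or `"condition"`.
#' @return data frame: group, n, q25, median, q75.
#' @export
aggregate_areas <- function(areas, by = c("week", "condition")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(areas), "fa_full_um2" %in% names(areas))
  if (nrow(areas) == 0) stop("no measurements to aggregate", call. = FALSE)
  if (!by %in% names(areas) || all(is.na(areas[[by]]))) {
    stop(sprintf("every measurement needs a `%s` label", by), call. = FALSE)
  }
  groups <- split(areas$fa_full_um2, areas[[by]])
  keys <- names(groups)
  ord <- if (by == "week") order(as.numeric(keys)) else order(keys)
  out <- do.call(rbind, lapply(groups[ord], function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), q25 = q[1], median = q[2], q75 = q[3])
  }))
  out <- cbind(setNames(data.frame(keys[ord], stringsAsFactors = FALSE), by), out)
  rownames(out) <- NULL
  out
}

#' Tricolour overlay of prediction against ground truth
#'
#' Blue marks truth-only pixels (missed), red prediction-only (false
#' positives), light green agreement; elsewhere the input image shows
#' through dimmed.
#'
#' @param image `(H, W, 3)` array.
#' @param pred,truth 0/1 masks.
#' @return `(H, W, 3)` RGB array.
#' @export
overlay_rgb <- function(image, pred, truth) {
  image <- to_rgb(as_hwc(image))
  out <- image * 0.6
  both <- pred == 1 & truth == 1
  only_p <- pred == 1 & truth == 0
  only_t <- pred == 0 & truth == 1
  paint <- function(x, sel, col) {
    for (ch in 1:3) {
      sl <- x[, , ch]; sl[sel] <- col[ch]; x[, , ch] <- sl
    }
    x
  }
  out <- paint(out, both, c(0.55, 0.95, 0.55))
  out <- paint(out, only_p, c(0.9, 0.15, 0.15))
  out <- paint(out, only_t, c(0.15, 0.25, 0.9))
  out
}

#' Segment a directory or manifest of images and quantify adipose area
#'
#' For every image: resize to the working resolution, predict a
#' probability map and thresholded mask, write the mask (and a tricolour
#' overlay when ground truth exists), and emit one area CSV row when
#' calibration metadata is present (images without a reference length get
#' an empty area cell and a warning, never a silent default). Per-image
#' failures are logged and skipped; the call errors only if every image
#' fails.
#'
#' @param model a trained `seg_model` or a checkpoint path.
#' @param input directory of images, a manifest CSV path, or a list of
#'   pairs from [load_manifest].
#' @param out_dir output directory.
#' @param target working resolution, default `c(256, 256)`; must be
#'   divisible by `2^depth` of the model.
#' @param threshold decision threshold.
#' @return data frame of per-image results (id, metadata, pixel counts,
#'   `fa_full_um2`), also written to `out_dir/areas.csv`.
#' @export
segment_directory <- function(model, input, out_dir, target = c(256, 256),
                              threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "seg_model"))
  pairs <- if (is.character(input) && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        full.names = TRUE, ignore.case = TRUE)
    lapply(files, function(f) {
      list(image = to_rgb(read_raster(f)), mask = NULL,
           id = tools::file_path_sans_ext(basename(f)),
           week = NA, condition = NA, stain = NA,
           reference_length = NA_real_)
    })
  } else if (is.character(input)) {
    load_manifest(input)
  } else {
    input
  }
  if (!length(pairs)) stop("no images to segment", call. = FALSE)
  dir.create(file.path(out_dir, "pred_masks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "overlays"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  failures <- 0L
  for (p in pairs) {
    res <- tryCatch({
      orig <- dim(p$image)[1:2]
      rz <- resize_pair(p$image, p$mask, target, depth = model$spec$depth)
      mask <- predict_mask(model, rz$image, threshold)
      png::writePNG(mask + 0, file.path(out_dir, "pred_masks",
                                        paste0(p$id, ".png")))
      if (!is.null(rz$mask)) {
        png::writePNG(overlay_rgb(rz$image, mask, rz$mask),
                      file.path(out_dir, "overlays", paste0(p$id, ".png")))
      }
      fa <- NA_real_; fa_down <- sum(mask)
      if (!is.null(p$reference_length) && !is.na(p$reference_length)) {
        am <- adipose_area(mask, prod(orig), p$reference_length)
        fa <- am$fa_full
      } else {
        warning(sprintf("image `%s` has no reference length; area left empty",
                        p$id), call. = FALSE)
      }
      data.frame(id = p$id, week = p$week %||% NA,
                 condition = p$condition %||% NA, stain = p$stain %||% NA,
                 fa_down_px = fa_down, ia_down_px = length(mask),
                 ia_full_px = prod(orig),
                 rl_um_per_px = p$reference_length %||% NA_real_,
                 fa_full_um2 = fa, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("image `%s` failed: %s", p$id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all images failed to segment", call. = FALSE)
  areas <- do.call(rbind, rows)
  write.csv(areas, file.path(out_dir, "areas.csv"), row.names = FALSE)
  areas
}
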