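#' Pixelwise confusion counts between two binary masks
#'
#' @param pred predicted mask, 0/1 matrix or array.
#' @param truth ground-truth mask, same shape, 0/1.
#' @return an object of class `confusion_counts`: integers `tp`, `fp`,
#'   `tn`, `fn` with `tp + fp + tn + fn == length(pred)`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("prediction and truth masks must have identical shapes", call. = FALSE)
  }
  assert_binary_mask(pred, "pred")
  assert_binary_mask(truth, "truth")
  p <- as.logical(pred); y <- as.logical(truth)
  structure(list(tp = sum(p & y), fp = sum(p & !y),
                 tn = sum(!p & !y), fn = sum(!p & y)),
            class = "confusion_counts")
}

# 1 when both defining sets are empty (a correct empty prediction), else 0
safe_ratio <- function(num, den, empty = NULL) {
  if (den > 0) return(num / den)
  if (empty) 1 else 0
}

#' Segmentation metrics from confusion counts
#'
#' Computes the seven standard binary-segmentation metrics: pixel accuracy
#' `(TP+TN)/total`; precision `TP/(TP+FP)`; recall (sensitivity)
#' `TP/(TP+FN)`; specificity `TN/(TN+FP)`; Dice coefficient
#' `2 x precision x recall / (precision + recall)` (equal to the F1 score
#' and to `2TP/(2TP+FP+FN)`); positive-class IOU (Jaccard index)
#' `TP/(TP+FP+FN)`; and overall IOU, the unweighted mean of the
#' positive-class and background-class IOUs.
#'
#' Zero-denominator convention: a metric is 1 when its defining sets are
#' both empty (e.g. no positives in the truth and none predicted), else 0.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return an object of class `metric_report`: a named list of the seven
#'   metrics plus the counts.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0), tp + fp + tn + fn > 0)
  total <- tp + fp + tn + fn
  iou_pos <- safe_ratio(tp, tp + fp + fn, empty = TRUE)
  iou_bg <- safe_ratio(tn, tn + fp + fn, empty = TRUE)
  structure(list(
    accuracy = (tp + tn) / total,
    precision = safe_ratio(tp, tp + fp, empty = (fn == 0)),
    recall = safe_ratio(tp, tp + fn, empty = (fp == 0)),
    specificity = safe_ratio(tn, tn + fp, empty = (fn == 0)),
    dice = safe_ratio(2 * tp, 2 * tp + fp + fn, empty = TRUE),
    iou_positive = iou_pos,
    iou_overall = (iou_pos + iou_bg) / 2,
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "metric_report")
}

#' Metrics for a prediction/truth mask pair
#'
#' Convenience wrapper: [confusion] followed by [metrics_from_counts].
#'
#' @inheritParams confusion
#' @return a `metric_report`.
#' @export
seg_metrics <- function(pred, truth) {
  metrics_from_counts(confusion(pred, truth))
}

metric_names <- c("accuracy", "precision", "recall", "specificity",
                  "dice", "iou_positive", "iou_overall")

#' Turn metric reports into a data frame
#'
#' @param reports a list of `metric_report` objects.
#' @param ... equal-length vectors of labels (e.g. `id`, `fold`, `seed`)
#'   prepended as columns.
#' @return data frame, one row per report: labels, counts, seven metrics.
#' @export
metrics_table <- function(reports, ...) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  labs <- list(...)
  df <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r[c("tp", "fp", "tn", "fn", metric_names)])
  }))
  if (length(labs)) df <- cbind(as.data.frame(labs), df)
  df
}

#' Summarise per-image metrics across folds and seeds
#'
#' Per-image metrics are first averaged within each (fold, seed) run, then
#' the mean and sample standard deviation (n - 1 denominator) are taken
#' across runs — the macro-averaging convention used for mean +/- SD
#' reporting.
#'
#' @param df data frame from [metrics_table] with `fold` and `seed`
#'   columns (a missing `seed` column is treated as a single seed).
#' @return data frame with one row per metric: `metric`, `mean`, `sd`,
#'   `n_runs`.
#' @export
summarize_metrics <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) > 0, "fold" %in% names(df))
  if (!"seed" %in% names(df)) df$seed <- 0L
  runs <- split(df, interaction(df$fold, df$seed, drop = TRUE))
  per_run <- do.call(rbind, lapply(runs, function(r) {
    colMeans(r[metric_names])
  }))
  data.frame(metric = metric_names,
             mean = colMeans(per_run),
             sd = if (nrow(per_run) > 1) apply(per_run, 2, sd) else 0,
             n_runs = nrow(per_run),
             row.names = NULL)
}
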