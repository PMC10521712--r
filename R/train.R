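# Training engine: weighted binary cross entropy, Adam with gradient
# clipping, early stopping with best-checkpoint restore, and the
# cross-validated experiment harness.

#' Training configuration
#'
#' Defaults follow the protocol used for 256x256 histology training:
#' 150 epochs, Adam at learning rate 0.001 with weight decay 1e-8,
#' gradient values clipped at 0.1, weighted BCE with positive-class weight
#' 3 (countering the heavy background imbalance), batch size 8, early
#' stopping after 10 epochs without validation improvement, and 8
#' independently augmented passes over the training set per epoch.
#'
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to gradients.
#' @param grad_clip clipping bound; values by default (`clip_mode="value"`),
#'   global norm with `clip_mode="norm"`.
#' @param clip_mode `"value"` or `"norm"`.
#' @param batch_size images per optimisation step.
#' @param pos_weight weight on the positive log-likelihood term.
#' @param patience early-stopping patience in epochs.
#' @param repeats_per_epoch augmented passes over the training set per epoch.
#' @param augment apply the random augmentation recipe to training images.
#' @param threshold decision threshold for validation metrics.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 150, learning_rate = 0.001,
                         weight_decay = 1e-8, grad_clip = 0.1,
                         clip_mode = c("value", "norm"), batch_size = 8,
                         pos_weight = 3, patience = 10,
                         repeats_per_epoch = 8, augment = TRUE,
                         threshold = 0.5) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(epochs >= 1, learning_rate >= 0, weight_decay >= 0,
            grad_clip > 0, batch_size >= 1, pos_weight > 0,
            patience >= 1, patience < epochs, repeats_per_epoch >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 clip_mode = clip_mode, batch_size = as.integer(batch_size),
                 pos_weight = pos_weight, patience = as.integer(patience),
                 repeats_per_epoch = as.integer(repeats_per_epoch),
                 augment = isTRUE(augment), threshold = threshold),
            class = "train_config")
}

#' Weighted binary cross entropy
#'
#' Mean over pixels of `-(w * y * log p + (1 - y) * log(1 - p))` with
#' `w = pos_weight`; `pos_weight = 1` is standard BCE. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param prob predicted probabilities in `(0, 1)`.
#' @param truth 0/1 mask of the same shape.
#' @param pos_weight weight on the positive term.
#' @return scalar loss (nonnegative).
#' @export
weighted_bce <- function(prob, truth, pos_weight = 1) {
  if (length(prob) != length(truth)) {
    stop("probability map and truth mask shapes disagree", call. = FALSE)
  }
  assert_binary_mask(truth)
  if (any(prob < 0 | prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(pos_weight * truth * log(p) + (1 - truth) * log(1 - p))
}

# gradient of the (clamped) weighted BCE w.r.t. the logits
wbce_grad_logits <- function(prob, truth, pos_weight) {
  n <- length(prob)
  g <- (prob * (1 + (pos_weight - 1) * truth) - pos_weight * truth) / n
  dim(g) <- dim(prob)
  g
}

# Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_grads <- function(grads, bound, mode) {
  if (mode == "value") {
    lapply(grads, function(g) pmin(pmax(g, -bound), bound))
  } else {
    nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (nrm > bound) lapply(grads, function(g) g * (bound / nrm)) else grads
  }
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate b into a elementwise (same names)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

loss_and_grads <- function(model, image, mask, pos_weight) {
  fw <- model_forward(model, image, want_cache = TRUE)
  y <- array(mask, dim(fw$prob))
  loss <- weighted_bce(fw$prob, y, pos_weight)
  gl <- wbce_grad_logits(fw$prob, y, pos_weight)
  list(loss = loss, grads = model_backward(model, fw$cache, gl))
}

validation_loss <- function(model, val_set, pos_weight) {
  mean(vapply(val_set, function(p) {
    fw <- model_forward(model, p$image)
    weighted_bce(fw$prob, array(p$mask, dim(fw$prob)), pos_weight)
  }, numeric(1)))
}

#' Train one model on one train/validation split
#'
#' Full protocol: per-step Adam updates on minibatch-averaged gradients of
#' the weighted BCE, gradient clipping, random augmentation of every
#' training image in every pass, per-epoch validation loss, early stopping
#' once the validation loss has not improved for `patience` epochs, and
#' restoration of the best-validation parameters. Fully seeded: data
#' order, augmentation draws and initialisation derive from `seed`.
#'
#' @param spec a [model_spec] (the model is built here so initialisation
#'   is governed by `seed`), or an already built `seg_model`.
#' @param train_set,val_set disjoint lists of pairs, each with `image`
#'   (`(H, W, 3)` array) and `mask` (0/1 matrix).
#' @param config a [train_config].
#' @param seed integer seed for initialisation, shuffling, augmentation.
#' @param fold,variant_label bookkeeping labels stored in the record.
#' @param verbose print per-epoch losses.
#' @return an object of class `run_record`: the trained `model` plus
#'   `history` (per-epoch train/val loss), `stopped_epoch`, `best_epoch`,
#'   `metrics` (per-validation-image [metrics_table]), labels.
#' @export
train_one <- function(spec, train_set, val_set, config = train_config(),
                      seed = 0L, fold = NA, variant_label = NULL,
                      verbose = FALSE) {
  stopifnot(length(train_set) >= 1, length(val_set) >= 1)
  model <- if (inherits(spec, "seg_model")) spec else build_model(spec, seed)
  set.seed(seed + 1L)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stopped <- config$epochs
  for (epoch in seq_len(config$epochs)) {
    epoch_losses <- c()
    for (rep in seq_len(config$repeats_per_epoch)) {
      ord <- sample(length(train_set))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bt in batches) {
        gacc <- NULL
        bl <- 0
        for (i in bt) {
          pair <- train_set[[i]]
          if (config$augment) {
            a <- augment(pair$image, pair$mask)
            pair <- list(image = a$image, mask = a$mask)
          }
          lg <- loss_and_grads(model, pair$image, pair$mask, config$pos_weight)
          if (!is.finite(lg$loss)) {
            stop(sprintf("non-finite training loss at epoch %d", epoch),
                 call. = FALSE)
          }
          gacc <- acc_grads(gacc, lg$grads)
          bl <- bl + lg$loss
        }
        gacc <- lapply(gacc, function(g) g / length(bt))
        gacc <- clip_grads(gacc, config$grad_clip, config$clip_mode)
        st <- adam_step(model$params, gacc, state, config$learning_rate,
                        config$weight_decay)
        model$params <- st$params
        state <- st$state
        epoch_losses <- c(epoch_losses, bl / length(bt))
      }
    }
    vl <- validation_loss(model, val_set, config$pos_weight)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(epoch_losses),
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(epoch_losses), vl))
    }
    if (vl < best$loss) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      stopped <- epoch
      break
    }
  }
  model$params <- best$params
  reports <- lapply(val_set, function(p) {
    seg_metrics(predict_mask(model, p$image, config$threshold), p$mask)
  })
  ids <- vapply(seq_along(val_set), function(i) {
    val_set[[i]]$id %||% sprintf("val_%02d", i)
  }, character(1))
  structure(list(model = model,
                 variant = variant_label %||% model$spec$variant,
                 fold = fold, seed = seed,
                 history = history, stopped_epoch = stopped,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 metrics = metrics_table(reports, id = ids,
                                         fold = rep(fold, length(ids)),
                                         seed = rep(seed, length(ids)))),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s fold=%s seed=%d  stopped@%d best@%d val_loss=%.4f mean dice=%.3f\n",
              x$variant, x$fold, x$seed, x$stopped_epoch, x$best_epoch,
              x$best_val_loss, mean(x$metrics$dice)))
  invisible(x)
}

#' Cross-validated experiment over models, folds and seeds
#'
#' Trains every (variant, fold, seed) triple, so e.g. 1 variant x 5 folds x
#' 3 seeds yields 15 run records. When `out_dir` is given, each completed
#' triple is saved as a checkpointed record and skipped on resume.
#'
#' @param specs list of [model_spec]s (one per variant).
#' @param dataset named list of pairs (names are image ids), each with
#'   `image` and `mask`.
#' @param folds a [make_folds] assignment over the dataset ids.
#' @param config a [train_config].
#' @param seeds integer vector of initialisation seeds (default 0:2).
#' @param out_dir optional directory for records and resume markers.
#' @param verbose print progress.
#' @return list with `records` (all run records) and `summary` (mean +/- SD
#'   of each metric per variant, plus parameter counts).
#' @export
run_experiment <- function(specs, dataset, folds, config = train_config(),
                           seeds = 0:2, out_dir = NULL, verbose = FALSE) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  stopifnot(inherits(folds, "fold_assignment"))
  fold_ids <- sort(unique(folds$fold[folds$fold > 0]))
  if (attr(folds, "scheme") == "validate_week8") fold_ids <- 1L
  records <- list()
  for (spec in specs) {
    for (fd in fold_ids) {
      sp <- fold_split(folds, fd)
      train_set <- dataset[sp$train]
      val_set <- dataset[sp$val]
      for (sd in seeds) {
        tag <- sprintf("%s_fold%s_seed%d", spec$variant, fd, sd)
        rec_path <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".rds"))
        if (!is.null(rec_path) && file.exists(rec_path)) {
          records[[tag]] <- readRDS(rec_path)
          next
        }
        if (verbose) message("training ", tag)
        rec <- train_one(spec, train_set, val_set, config, seed = sd,
                         fold = fd, verbose = FALSE)
        records[[tag]] <- rec
        if (!is.null(rec_path)) {
          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(rec, rec_path)
        }
      }
    }
  }
  per_variant <- split(records, vapply(records, `[[`, "", "variant"))
  summary <- do.call(rbind, lapply(names(per_variant), function(v) {
    df <- do.call(rbind, lapply(per_variant[[v]], `[[`, "metrics"))
    s <- summarize_metrics(df)
    s$variant <- v
    s$parameters <- count_parameters(per_variant[[v]][[1]]$model)
    s
  }))
  list(records = records, summary = summary)
}
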