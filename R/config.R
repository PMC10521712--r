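# YAML experiment configuration: a single file with `model`, `data`,
# `folds` and `training` sections, consumed by the command-line interface
# and usable programmatically.

#' Read an experiment configuration from YAML
#'
#' Recognised sections (all optional, with package defaults):
#'
#' ```yaml
#' model:
#'   variant: joshua_plus
#'   depth: 4
#'   base_channels: 64
#'   seed: 0
#'   histogram: {bins: 16, window: [2, 2], spatial_mode: preserve, span: [-2, 2]}
#' folds: {scheme: random_kfold, k: 5, seed: 0}
#' training:
#'   epochs: 150
#'   learning_rate: 0.001
#'   weight_decay: 1.0e-8
#'   grad_clip: 0.1
#'   batch_size: 8
#'   pos_weight: 3
#'   patience: 10
#'   repeats: 8
#'   seeds: [0, 1, 2]
#' ```
#'
#' @param path YAML file path.
#' @return list with `model_spec` (a [model_spec]), `model_seed`,
#'   `train` (a [train_config]), `seeds`, `folds` (scheme/k/seed list).
#' @export
read_config <- function(path) {
  cf <- yaml::read_yaml(path)
  m <- cf$model %||% list()
  h <- m$histogram %||% list()
  spec <- model_spec(
    variant = m$variant %||% "unet",
    depth = m$depth %||% 4,
    base_channels = m$base_channels %||% 64,
    bins = h$bins %||% 16,
    window = unlist(h$window %||% c(2, 2)),
    spatial_mode = h$spatial_mode %||% "preserve",
    hist_span = unlist(h$span %||% c(-2, 2))
  )
  tr <- cf$training %||% list()
  train <- train_config(
    epochs = tr$epochs %||% 150,
    learning_rate = tr$learning_rate %||% 0.001,
    weight_decay = tr$weight_decay %||% 1e-8,
    grad_clip = tr$grad_clip %||% 0.1,
    clip_mode = tr$clip_mode %||% "value",
    batch_size = tr$batch_size %||% 8,
    pos_weight = tr$pos_weight %||% 3,
    patience = tr$patience %||% 10,
    repeats_per_epoch = tr$repeats %||% 8,
    augment = tr$augment %||% TRUE
  )
  f <- cf$folds %||% list()
  list(model_spec = spec,
       model_seed = m$seed %||% 0L,
       train = train,
       seeds = unlist(tr$seeds %||% 0:2),
       folds = list(scheme = f$scheme %||% "random_kfold",
                    k = f$k %||% 5, seed = f$seed %||% 0L))
}
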