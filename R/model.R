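#' Training configuration for the quantile forecaster
#'
#' Hyperparameters of the two-stage training protocol: a population model is
#' trained first on aggregated data (learning rate `pretrain_lr`), then
#' fine-tuned per individual at the lower `finetune_lr`.  Both stages use
#' Adam, batch size 128, at most `max_epochs` epochs and early stopping on
#' the chronological validation split (patience 20 epochs, minimum
#' improvement `min_delta`).
#'
#' @param lstm_cells LSTM cells in encoder and decoder (64).
#' @param pretrain_lr,finetune_lr Learning rates of the two stages.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs).
#' @param min_delta Minimum validation-loss improvement counted as progress.
#' @param split Fraction of each individual's windows used for training; the
#'   chronological remainder is the validation split.
#' @param quantiles Lower, median and upper quantile levels of the three
#'   output heads.
#' @param enc_len Encoder history length in 5-min steps.
#' @param clip_norm Global gradient-norm clip.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(lstm_cells = 64L,
                            pretrain_lr = 1e-3,
                            finetune_lr = 1e-4,
                            batch_size = 128L,
                            max_epochs = 100L,
                            patience = 20L,
                            min_delta = 1e-4,
                            split = 0.8,
                            quantiles = c(0.025, 0.5, 0.975),
                            enc_len = 24L,
                            clip_norm = 1.0,
                            seed = 42L) {
  q <- quantiles
  if (length(q) != 3 || !(0 < q[1] && q[1] < 0.5 && q[2] == 0.5 &&
                          0.5 < q[3] && q[3] < 1)) {
    abort("`quantiles` must be (lower, 0.5, upper) with 0 < lower < 0.5 < upper < 1")
  }
  if (split <= 0 || split >= 1) abort("`split` must lie inside (0, 1)")
  structure(as.list(environment())[c(
    "lstm_cells", "pretrain_lr", "finetune_lr", "batch_size", "max_epochs",
    "patience", "min_delta", "split", "quantiles", "enc_len", "clip_norm",
    "seed")], class = "training_config")
}

# chronological train/validation row indices for one window set
chrono_split <- function(n, split) {
  n_train <- max(1L, min(n - 1L, floor(n * split)))
  val <- if (n_train < n) seq(n_train + 1L, n) else integer(0)
  list(train = seq_len(n_train), val = val)
}

new_bundle <- function(params, config, stats, fit, val_mae, stage) {
  structure(list(
    params = params, config = config, stats = stats,
    history = tibble(epoch = seq_along(fit$train_loss),
                     train_loss = as.numeric(fit$train_loss),
                     val_loss = as.numeric(fit$val_loss),
                     stage = stage),
    best_epoch = fit$best_epoch,
    val_loss = fit$best_val_loss,
    validation_mae = val_mae,
    stage = stage), class = "qseq2seq")
}

# median-head MAE (mg/dL) at the final decoder step over window rows `idx`
val_mae_mgdl <- function(params, windows, idx, stats) {
  if (length(idx) == 0) return(NA_real_)
  w <- subset_windows(windows, idx)
  pred <- .ms_predict(params, w$x_enc, w$x_dec)
  tdec <- dim(pred)[2]
  med <- denorm_glucose(pred[, tdec, 2], stats)
  obs <- denorm_glucose(w$y[, tdec], stats)
  mean(abs(med - obs))
}

#' Train the population (generalised) forecaster
#'
#' Stage one of the two-stage protocol: pools windows from every individual's
#' chronological training split (normalisation statistics are computed on
#' those splits and frozen into the returned bundle), then minimises the
#' uniformly weighted multitask pinball loss with Adam and early stopping on
#' the pooled validation split.
#'
#' @param data A `meal_timeline` or list of them (one per individual).
#' @param config A [training_config()].
#' @return A `qseq2seq` model bundle; see [glance.qseq2seq()].
#' @export
train_population <- function(data, config = training_config()) {
  if (inherits(data, "data.frame")) data <- list(data)
  if (length(data) < 1) abort("need at least one timeline")
  n_train_steps <- purrr::map_int(data, function(tl) {
    as.integer(floor(nrow(tl) * config$split))
  })
  stats <- window_stats(data, n_steps = max(n_train_steps))
  ws <- purrr::map(data, build_windows, enc_len = config$enc_len, stats = stats)
  splits <- purrr::map(ws, function(w) {
    chrono_split(nrow(w$y), config$split)
  })
  all_w <- bind_windows(ws)
  offs <- cumsum(c(0, purrr::map_int(ws, ~ nrow(.x$y))))
  train_idx <- unlist(purrr::map2(splits, offs[-length(offs)],
                                  ~ .x$train + .y))
  val_idx <- unlist(purrr::map2(splits, offs[-length(offs)], ~ .x$val + .y))

  fit <- .ms_train(
    .ms_init_params(3L, 2L, config$lstm_cells, config$seed),
    all_w$x_enc, all_w$x_dec, all_w$y,
    as.integer(train_idx - 1L), as.integer(val_idx - 1L),
    config$quantiles, config$pretrain_lr, config$batch_size,
    config$max_epochs, config$patience, config$min_delta,
    config$clip_norm, derive_seed(config$seed, "shuffle"))

  mae <- val_mae_mgdl(fit$params, all_w, val_idx, stats)
  new_bundle(fit$params, config, stats, fit, mae, "population")
}

#' Fine-tune the population forecaster on one individual
#'
#' Stage two: continues training from a population bundle on a single
#' individual's windows at the reduced `finetune_lr`, keeping the population
#' normalisation statistics frozen.  The returned bundle's
#' `validation_mae` — the median-head mean absolute error on the individual's
#' chronological validation split, in mg/dL — is the threshold used by the
#' carbohydrate estimator.  With `max_epochs = 0` the weights are unchanged
#' and only the validation MAE is recomputed.
#'
#' @param bundle A population `qseq2seq` bundle from [train_population()].
#' @param data The individual's `meal_timeline`.
#' @param config Optional [training_config()]; defaults to the bundle's.
#' @return An individualised `qseq2seq` bundle.
#' @export
finetune_individual <- function(bundle, data, config = NULL) {
  if (!inherits(bundle, "qseq2seq")) abort("`bundle` must be a qseq2seq model")
  config <- config %||% bundle$config
  w <- build_windows(data, enc_len = config$enc_len, stats = bundle$stats)
  sp <- chrono_split(nrow(w$y), config$split)
  if (config$max_epochs == 0) {
    mae <- val_mae_mgdl(bundle$params, w, sp$val, bundle$stats)
    out <- bundle
    out$validation_mae <- mae
    out$stage <- "individual"
    return(out)
  }
  fit <- .ms_train(
    bundle$params, w$x_enc, w$x_dec, w$y,
    as.integer(sp$train - 1L), as.integer(sp$val - 1L),
    config$quantiles, config$finetune_lr, config$batch_size,
    config$max_epochs, config$patience, config$min_delta,
    config$clip_norm, derive_seed(config$seed, "finetune"))
  mae <- val_mae_mgdl(fit$params, w, sp$val, bundle$stats)
  new_bundle(fit$params, config, bundle$stats, fit, mae, "individual")
}

# fast path: one window, returns 4 x 3 matrix of de-normalised quantiles
predict_raw <- function(bundle, x_enc, x_dec) {
  p <- .ms_predict(bundle$params,
                   array(x_enc, c(1L, dim(x_enc))),
                   array(x_dec, c(1L, dim(x_dec))))
  denorm_glucose(matrix(p[1, , ], ncol = 3), bundle$stats)
}

#' Predict quantile glucose trajectories
#'
#' De-normalised 20-min (4-step) forecasts of the lower, median and upper
#' glucose quantiles for every window in a window set.
#'
#' @param bundle A `qseq2seq` bundle.
#' @param windows A `meal_windows` object built with the bundle's statistics.
#' @return A tibble with columns `window`, `step` (1-4), `target_step`,
#'   `lower`, `median`, `upper` (mg/dL).
#' @export
predict_quantiles <- function(bundle, windows) {
  if (!inherits(windows, "meal_windows")) {
    abort("`windows` must come from build_windows()")
  }
  if (dim(windows$x_enc)[2] != bundle$config$enc_len) {
    abort("window encoder length does not match the model")
  }
  n <- nrow(windows$y)
  if (n == 0) {
    return(tibble(window = integer(), step = integer(),
                  target_step = integer(), lower = numeric(),
                  median = numeric(), upper = numeric()))
  }
  p <- .ms_predict(bundle$params, windows$x_enc, windows$x_dec)
  tdec <- dim(p)[2]
  out <- tidyr::expand_grid(window = seq_len(n), step = seq_len(tdec)) |>
    dplyr::mutate(
      target_step = windows$target_step[.data$window],
      lower = denorm_glucose(as.vector(t(p[, , 1])), bundle$stats),
      median = denorm_glucose(as.vector(t(p[, , 2])), bundle$stats),
      upper = denorm_glucose(as.vector(t(p[, , 3])), bundle$stats))
  class(out) <- c("quantile_forecast", class(out))
  out
}

#' Empirical prediction-interval coverage
#'
#' Fraction (as a percentage) of observed glucose values falling inside the
#' `[lower, upper]` forecast interval at the final decoder step, the step
#' aligned with the present CGM sample.
#'
#' @param bundle A `qseq2seq` bundle.
#' @param windows A `meal_windows` object.
#' @param idx Optional window rows to evaluate (defaults to all).
#' @return Coverage in percent.
#' @export
interval_coverage <- function(bundle, windows, idx = NULL) {
  if (!is.null(idx)) windows <- subset_windows(windows, idx)
  p <- .ms_predict(bundle$params, windows$x_enc, windows$x_dec)
  tdec <- dim(p)[2]
  lo <- denorm_glucose(p[, tdec, 1], bundle$stats)
  hi <- denorm_glucose(p[, tdec, 3], bundle$stats)
  obs <- denorm_glucose(windows$y[, tdec], bundle$stats)
  100 * mean(obs >= lo & obs <= hi)
}

#' Estimation threshold from validation error
#'
#' The carbohydrate-search stopping threshold: the mean absolute error
#' between reference glucose and the median-quantile prediction over a
#' validation set.
#'
#' @param targets Reference glucose values (mg/dL).
#' @param median_predictions Median-head predictions (mg/dL).
#' @return The mean absolute error (mg/dL).
#' @export
compute_epsilon <- function(targets, median_predictions) {
  if (length(targets) == 0 || length(targets) != length(median_predictions)) {
    abort("`targets` and `median_predictions` must be equal-length, non-empty")
  }
  mean(abs(targets - median_predictions))
}

#' @export
print.qseq2seq <- function(x, ...) {
  cat(sprintf(paste0(
    "<qseq2seq %s model: %d LSTM cells, quantiles (%s)>\n",
    "  best epoch %d, validation loss %.5f, validation MAE %.2f mg/dL\n"),
    x$stage, x$config$lstm_cells,
    paste(x$config$quantiles, collapse = ", "),
    x$best_epoch, x$val_loss, x$validation_mae))
  invisible(x)
}
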