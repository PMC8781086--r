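#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a forecaster
#'
#' @param x A `qseq2seq` bundle.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `stage`.
#' @export
tidy.qseq2seq <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted forecaster
#'
#' @param x A `qseq2seq` bundle.
#' @param ... Unused.
#' @return A one-row tibble: `stage`, `epochs`, `best_epoch`, `val_loss`,
#'   `validation_mae`, `lstm_cells`, `n_params`.
#' @export
glance.qseq2seq <- function(x, ...) {
  tibble(stage = x$stage,
         epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         val_loss = x$val_loss,
         validation_mae = x$validation_mae,
         lstm_cells = x$config$lstm_cells,
         n_params = sum(purrr::map_int(x$params, length)))
}

#' Tidy a detection-matching result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return The per-true-positive `matches` tibble.
#' @export
tidy.match_result <- function(x, ...) {
  x$matches
}

#' One-row summary of a detection-matching result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return A one-row tibble with counts, precision/recall (percent),
#'   F-score and the median and mean +/- SD detection delay (min).
#' @export
glance.match_result <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn,
         precision = precision(x), recall = recall(x), fscore = fscore(x),
         median_delay_min = if (length(x$delays)) stats::median(x$delays) else NA_real_,
         mean_delay_min = if (length(x$delays)) mean(x$delays) else NA_real_,
         sd_delay_min = if (length(x$delays) > 1) stats::sd(x$delays) else NA_real_)
}

#' Tidy a closed-loop run
#'
#' @param x A `loop_result`.
#' @param ... Unused.
#' @return The per-flag detection log tibble.
#' @export
tidy.loop_result <- function(x, ...) {
  x$detections
}

#' One-row summary of a closed-loop run
#'
#' @param x A `loop_result`.
#' @param ... Unused.
#' @return A one-row tibble: mode, flags, accepted estimates, total insulin
#'   (U) and the glycaemic summary of the true glucose trace.
#' @export
glance.loop_result <- function(x, ...) {
  tl <- x$timeline
  dplyr::bind_cols(
    tibble(mode = x$mode,
           n_flags = nrow(x$detections),
           n_accepted = sum(x$detections$accepted),
           total_insulin_u = sum(tl$basal_uhr * 5 / 60 + tl$bolus_u)),
    glycaemic_summary(tl$true_bg_mgdl))
}
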