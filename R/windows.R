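# Sliding forecast windows over a timeline.
#
# A window targeting step t holds:
#   encoder inputs  (glucose, insulin, carbs) at steps t-enc_len-3 ... t-4
#   decoder inputs  (insulin, carbs)          at steps t-3 ... t
#   targets         glucose                   at steps t-3 ... t
# The glucose channel is the CGM signal, insulin is the units delivered per
# 5-min step (basal * 5/60 + bolus) and the meal channel is the meal record
# (carbs_g): in simulator-generated training data this is the true meal
# schedule, while the announcement behaviour (skips, delays, counting
# errors) corrupts only the insulin channel — which decorrelates the two
# inputs and lets the network identify the carbohydrate response the
# inverse-search estimator relies on.  During fully closed-loop deployment
# the harness fills the same channel with the estimated meals.  Features are
# min-max normalised to [0, 1] with statistics frozen at population-training
# time.

DEC_LEN <- 4L

timeline_features <- function(timeline) {
  list(glucose = timeline$cgm_mgdl,
       insulin = timeline$basal_uhr * (5 / 60) + timeline$bolus_u,
       carbs = timeline$carbs_g)
}

#' Normalisation statistics for forecaster features
#'
#' Per-feature min-max offset/scale over one or more timelines (glucose,
#' insulin, carbs channels).  Zero-range features get unit scale.
#'
#' @param timelines A `meal_timeline` or list of them.
#' @param n_steps Optional number of leading steps of each timeline to use
#'   (so statistics can be confined to the training split).
#' @return A `window_stats` list with `offset` and `scale` per feature.
#' @export
window_stats <- function(timelines, n_steps = NULL) {
  if (inherits(timelines, "data.frame")) timelines <- list(timelines)
  feats <- purrr::map(timelines, function(tl) {
    f <- timeline_features(tl)
    if (!is.null(n_steps)) f <- purrr::map(f, ~ .x[seq_len(min(n_steps, length(.x)))])
    f
  })
  nm <- c("glucose", "insulin", "carbs")
  offset <- scale <- stats::setNames(numeric(3), nm)
  for (f in nm) {
    v <- unlist(purrr::map(feats, f))
    offset[f] <- min(v)
    rng <- max(v) - min(v)
    scale[f] <- if (rng > 0) rng else 1
  }
  structure(list(offset = offset, scale = scale), class = "window_stats")
}

norm_feat <- function(x, stats, feature) {
  (x - stats$offset[[feature]]) / stats$scale[[feature]]
}

denorm_glucose <- function(x, stats) {
  x * stats$scale[["glucose"]] + stats$offset[["glucose"]]
}

#' Build sliding forecast windows from a timeline
#'
#' Stride-1 sliding windows for the sequence-to-sequence forecaster; see the
#' package vignette for the window layout.  Returns an empty window set with
#' a warning when the timeline is shorter than `enc_len + 4` steps.
#'
#' @param timeline A `meal_timeline`.
#' @param enc_len Encoder history length in 5-min steps (default 24 = 2 h).
#' @param stats A `window_stats` object; computed from `timeline` itself when
#'   `NULL` (training-time statistics should be passed explicitly).
#' @return A `meal_windows` object: arrays `x_enc` (n, enc_len, 3), `x_dec`
#'   (n, 4, 2), matrix `y` (n, 4) of normalised targets, the `stats` used,
#'   and `target_step` giving the timeline step index of each window's final
#'   decoder step.
#' @export
build_windows <- function(timeline, enc_len = 24L, stats = NULL) {
  enc_len <- as.integer(enc_len)
  if (enc_len < 1) abort("`enc_len` must be >= 1")
  n <- nrow(timeline)
  need <- enc_len + DEC_LEN
  if (is.null(stats)) stats <- window_stats(timeline)
  if (n < need) {
    warn(sprintf("timeline has %d steps, fewer than enc_len + 4 = %d; no windows",
                 n, need))
    return(structure(list(
      x_enc = array(0, c(0, enc_len, 3)), x_dec = array(0, c(0, DEC_LEN, 2)),
      y = matrix(0, 0, DEC_LEN), stats = stats, enc_len = enc_len,
      target_step = integer(0)), class = "meal_windows"))
  }
  f <- timeline_features(timeline)
  g <- norm_feat(f$glucose, stats, "glucose")
  ins <- norm_feat(f$insulin, stats, "insulin")
  cb <- norm_feat(f$carbs, stats, "carbs")

  nw <- n - need + 1L
  targets <- seq(need, n)                       # target step t per window
  x_enc <- array(0, c(nw, enc_len, 3))
  for (j in seq_len(enc_len)) {
    rows <- targets - need + j                  # step t - enc_len - 4 + j
    x_enc[, j, 1] <- g[rows]
    x_enc[, j, 2] <- ins[rows]
    x_enc[, j, 3] <- cb[rows]
  }
  x_dec <- array(0, c(nw, DEC_LEN, 2))
  y <- matrix(0, nw, DEC_LEN)
  for (j in seq_len(DEC_LEN)) {
    rows <- targets - DEC_LEN + j
    x_dec[, j, 1] <- ins[rows]
    x_dec[, j, 2] <- cb[rows]
    y[, j] <- g[rows]
  }
  structure(list(x_enc = x_enc, x_dec = x_dec, y = y, stats = stats,
                 enc_len = enc_len, target_step = targets),
            class = "meal_windows")
}

#' @export
print.meal_windows <- function(x, ...) {
  cat(sprintf("<meal_windows: %d windows, encoder %d steps, decoder %d steps>\n",
              nrow(x$y), x$enc_len, ncol(x$y)))
  invisible(x)
}

# row-subset of a window set (keeps stats/enc_len)
subset_windows <- function(w, idx) {
  structure(list(x_enc = w$x_enc[idx, , , drop = FALSE],
                 x_dec = w$x_dec[idx, , , drop = FALSE],
                 y = w$y[idx, , drop = FALSE], stats = w$stats,
                 enc_len = w$enc_len, target_step = w$target_step[idx]),
            class = "meal_windows")
}

# concatenate window sets that share stats/enc_len
bind_windows <- function(ws) {
  structure(list(
    x_enc = do.call(abind3, purrr::map(ws, "x_enc")),
    x_dec = do.call(abind3, purrr::map(ws, "x_dec")),
    y = do.call(rbind, purrr::map(ws, "y")),
    stats = ws[[1]]$stats, enc_len = ws[[1]]$enc_len,
    target_step = unlist(purrr::map(ws, "target_step"))),
    class = "meal_windows")
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1]
    if (na > 0) out[at + seq_len(na), , ] <- a
    at <- at + na
  }
  out
}
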