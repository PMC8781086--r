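#' Physiological-dynamics check for the carbohydrate search
#'
#' Increasing the candidate meal size must move the median forecast towards
#' the observed CGM; if the error fails to decrease across two successive
#' coarse increments the candidate meal cannot explain the excursion and the
#' estimate is discarded.
#'
#' @param error_trace Forecast errors (mg/dL) recorded at successive coarse
#'   increments, at least two.
#' @return `TRUE` when the error is strictly decreasing throughout, `FALSE`
#'   (discard) otherwise.
#' @export
verify_dynamics <- function(error_trace) {
  if (length(error_trace) < 2) {
    abort("need at least two coarse iterations to verify dynamics")
  }
  all(diff(error_trace) < 0)
}

# Iterative inverse search over the meal input.  `error_fn(grams)` returns
# the absolute error (mg/dL) between the median forecast and the present CGM
# with `grams` injected at the inferred onset.  Coarse phase ascends in
# `coarse`-g increments until the error drops below `epsilon` or the cap is
# hit, discarding the estimate if an increment fails to reduce the error;
# the fine phase backs off one coarse increment and ascends in `fine`-g
# steps to the first size meeting the threshold.
meal_search <- function(error_fn, epsilon, m_max = 90, coarse = 10, fine = 1) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    abort("`epsilon` must be a positive threshold (degenerate otherwise)")
  }
  iter <- 0L
  err0 <- error_fn(0)
  if (err0 <= epsilon) {
    return(tibble(grams = 0, final_error = err0, iterations = iter,
                  capped = FALSE, discarded = FALSE))
  }
  trace <- err0
  m <- 0
  err <- err0
  repeat {
    if (m >= m_max) {  # nothing on the grid explains the deviation
      return(tibble(grams = m_max, final_error = err, iterations = iter,
                    capped = TRUE, discarded = FALSE))
    }
    m <- min(m_max, m + coarse)
    err <- error_fn(m)
    iter <- iter + 1L
    trace <- c(trace, err)
    if (!verify_dynamics(utils::tail(trace, 2))) {
      return(tibble(grams = 0, final_error = err, iterations = iter,
                    capped = FALSE, discarded = TRUE))
    }
    if (err <= epsilon) break
  }
  # fine phase: re-run the last coarse step in 1-g increments
  m_fine <- max(0, m - coarse)
  for (g in seq(m_fine + fine, m, by = fine)) {
    err <- error_fn(g)
    iter <- iter + 1L
    if (err <= epsilon) {
      return(tibble(grams = g, final_error = err, iterations = iter,
                    capped = g >= m_max, discarded = FALSE))
    }
  }
  tibble(grams = m, final_error = err, iterations = iter,
         capped = m >= m_max, discarded = FALSE)
}

#' Estimate the carbohydrate content of a detected meal
#'
#' Given an active meal flag, searches over candidate meal sizes injected
#' into the forecaster's carbohydrate input at the inferred meal onset until
#' the median forecast at the present sample matches the observed CGM to
#' within `epsilon` (the individual's validation MAE).  The search ascends in
#' 10-g increments, then refines in 1-g increments from one coarse step
#' back; estimates are capped at 90 g, and discarded when increasing the
#' meal input fails to reduce the error (the excursion then violates the
#' expected carbohydrate dynamics).
#'
#' @param bundle A `qseq2seq` bundle.
#' @param x_enc,x_dec Normalised encoder/decoder inputs of the window whose
#'   final decoder step is the present sample (`enc_len` x 3 and 4 x 2
#'   matrices, as stored in a `meal_windows` row).
#' @param cgm_now Present CGM sample (mg/dL).
#' @param epsilon Stopping threshold (mg/dL); see [compute_epsilon()].
#' @param onset_offset Steps before the present sample at which the candidate
#'   meal is injected (default 4: two persistence samples before the first
#'   exceedance of a just-raised flag).
#' @param m_max Maximum meal size per estimate (g).
#' @return A one-row tibble: `grams`, `final_error`, `iterations`, `capped`,
#'   `discarded`.
#' @export
estimate_meal <- function(bundle, x_enc, x_dec, cgm_now, epsilon,
                          onset_offset = 4L, m_max = 90) {
  enc_len <- nrow(x_enc)
  dec_len <- nrow(x_dec)
  scale <- bundle$stats$scale[["carbs"]]
  # position of the onset inside the window: offset 0 is the final decoder
  # step; offsets < dec_len fall in the decoder, larger ones in the encoder
  off <- as.integer(onset_offset)
  error_fn <- function(grams) {
    xe <- x_enc
    xd <- x_dec
    g_norm <- grams / scale
    if (off < dec_len) {
      xd[dec_len - off, 2] <- xd[dec_len - off, 2] + g_norm
    } else {
      j <- enc_len - (off - dec_len)
      j <- min(enc_len, max(1L, j))
      xe[j, 3] <- xe[j, 3] + g_norm
    }
    pred <- predict_raw(bundle, xe, xd)
    abs(pred[dec_len, 2] - cgm_now)
  }
  meal_search(error_fn, epsilon, m_max = m_max)
}
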