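#' Meal-detector configuration
#'
#' A meal flag is raised when the CGM exceeds the forecast upper bound for
#' more than `persistence_n` consecutive samples (i.e. on the third
#' consecutive exceedance with the default `persistence_n = 2`) while the
#' glucose rate of change is at least `roc_threshold` mg/dL/min, and no
#' accepted estimate lies within the `refractory_min` window.
#'
#' @param persistence_n Flag requires the consecutive-exceedance count `k` to
#'   exceed this value.
#' @param roc_threshold Minimum glucose rate of change (mg/dL/min).
#' @param roc_window Number of recent CGM samples used for the least-squares
#'   rate of change.
#' @param refractory_min Minutes after an accepted estimate during which no
#'   new flag is raised.
#' @return A `detector_config` list.
#' @export
detector_config <- function(persistence_n = 2L,
                            roc_threshold = 1.0,
                            roc_window = 3L,
                            refractory_min = 60) {
  if (persistence_n < 0) abort("`persistence_n` must be >= 0")
  if (roc_threshold < 0) abort("`roc_threshold` must be >= 0")
  if (roc_window < 2) abort("`roc_window` must be >= 2")
  if (refractory_min < 0) abort("`refractory_min` must be >= 0")
  structure(list(persistence_n = as.integer(persistence_n),
                 roc_threshold = roc_threshold,
                 roc_window = as.integer(roc_window),
                 refractory_min = refractory_min),
            class = "detector_config")
}

#' Fresh detector state
#'
#' @return A `detection_state` list: consecutive-exceedance count `k`, the
#'   time of the first sample of the current exceedance run, the last flag
#'   time and the last accepted-estimate time (all minutes, `NA` when unset).
#' @export
new_detection_state <- function() {
  structure(list(k = 0L,
                 first_exceed_min = NA_real_,
                 last_flag_min = NA_real_,
                 last_accept_min = NA_real_),
            class = "detection_state")
}

#' Glucose rate of change
#'
#' Least-squares slope of the most recent CGM samples, in mg/dL/min.  Damps
#' single-sample sensor noise relative to a backward difference.
#'
#' @param cgm Recent CGM samples (mg/dL), oldest first, at `step_min`
#'   spacing; the slope uses the trailing `window` samples.
#' @param step_min Sample spacing in minutes.
#' @param window Number of trailing samples (default: all supplied).
#' @return Slope in mg/dL/min.
#' @export
rate_of_change <- function(cgm, step_min = 5, window = length(cgm)) {
  if (length(cgm) < 2) abort("need at least 2 CGM samples for a slope")
  y <- utils::tail(cgm, window)
  x <- seq_along(y) * step_min
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Advance the meal detector by one CGM sample
#'
#' Increments the consecutive-exceedance count `k` when the current CGM
#' sample exceeds the forecast upper bound at its final step (the step
#' aligned with the present sample), and resets it to zero otherwise.  A
#' flag is raised when `k > persistence_n`, the rate of change is at least
#' `roc_threshold`, and the sample is outside the refractory window of the
#' last accepted estimate; raising a flag resets `k`, so a further flag needs
#' a fresh persistent exceedance run.
#'
#' @param state A `detection_state`.
#' @param upper_bound Upper-quantile forecast aligned with the current
#'   sample (mg/dL): either the scalar final-step value or the 4-step vector,
#'   of which the last entry is used.
#' @param cgm_now Current CGM sample (mg/dL).
#' @param roc Current glucose rate of change (mg/dL/min), from
#'   [rate_of_change()].
#' @param config A [detector_config()].
#' @param time_min Current time in minutes.
#' @return `list(state = <updated state>, flag = <logical>)`.
#' @export
update_detector <- function(state, upper_bound, cgm_now, roc, config,
                            time_min) {
  ub <- upper_bound[length(upper_bound)]
  if (cgm_now > ub) {
    if (state$k == 0L) state$first_exceed_min <- time_min
    state$k <- state$k + 1L
  } else {
    state$k <- 0L
    state$first_exceed_min <- NA_real_
  }
  in_refractory <- !is.na(state$last_accept_min) &&
    (time_min - state$last_accept_min) < config$refractory_min
  flag <- state$k > config$persistence_n &&
    roc >= config$roc_threshold &&
    !in_refractory
  if (flag) {
    state$last_flag_min <- time_min
    state$flag_first_exceed_min <- state$first_exceed_min
    state$flag_k <- state$k
    state$k <- 0L
    state$first_exceed_min <- NA_real_
  }
  list(state = state, flag = flag)
}
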