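#' Pinball (tilted) loss
#'
#' Asymmetric loss whose minimiser is the `tau`-quantile of the conditional
#' distribution of `y`: `tau * (y - y_hat)` when the observation exceeds the
#' prediction and `(1 - tau) * (y_hat - y)` otherwise.  At `tau = 0.5` it
#' equals half the absolute error.  Vectorised elementwise with the usual
#' recycling.
#'
#' @param y Observed values (mg/dL).
#' @param y_hat Predicted values (mg/dL).
#' @param tau Quantile level, strictly inside (0, 1).
#' @return Elementwise non-negative losses.
#' @export
pinball_loss <- function(y, y_hat, tau) {
  stop_if_not_scalar_number(tau, "tau")
  if (tau <= 0 || tau >= 1) abort("`tau` must lie strictly inside (0, 1)")
  d <- y - y_hat
  ifelse(d > 0, tau * d, (1 - tau) * (-d))
}

#' Total multitask quantile loss
#'
#' Uniformly weighted combination of the three per-quantile batch losses:
#' `(L_LB + L_M + L_UB) / 3`.  Vector inputs are averaged first, so each
#' argument may be either a scalar batch loss or the elementwise losses of a
#' batch.
#'
#' @param losses_lb,losses_m,losses_ub Lower-bound, median and upper-bound
#'   quantile losses.
#' @return A single loss value.
#' @export
total_loss <- function(losses_lb, losses_m, losses_ub) {
  (mean(losses_lb) + mean(losses_m) + mean(losses_ub)) / 3
}
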