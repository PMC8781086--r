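#' Meal protocol for a simulated day
#'
#' Four daily meal slots with the mean carbohydrate sizes and clock times of
#' the evaluation scenario: 70 g breakfast at 07:00, 100 g lunch at 13:00, a
#' 30 g snack at 17:00 and an 80 g dinner at 20:00.  Day-to-day variability is
#' Gaussian: meal onset times have standard deviation `time_sd` minutes and
#' meal sizes a coefficient of variation `size_cv`.
#'
#' @param mean_sizes Named numeric vector of mean carbohydrate sizes (g), one
#'   per slot, in clock order.
#' @param mean_times_min Clock time of each slot in minutes after midnight.
#' @param time_sd Standard deviation of meal onset time (min).
#' @param size_cv Coefficient of variation of meal size (fraction).
#' @return A `meal_protocol` list.
#' @export
meal_protocol <- function(mean_sizes = c(breakfast = 70, lunch = 100,
                                         snack = 30, dinner = 80),
                          mean_times_min = c(7, 13, 17, 20) * 60,
                          time_sd = 60,
                          size_cv = 0.10) {
  if (length(mean_sizes) != length(mean_times_min)) {
    abort("`mean_sizes` and `mean_times_min` must have one entry per slot")
  }
  if (any(mean_sizes <= 0)) abort("meal sizes must be positive")
  if (is.unsorted(mean_times_min, strictly = TRUE)) {
    abort("meal slots must be ordered by clock time")
  }
  if (time_sd < 0 || size_cv < 0) abort("`time_sd` and `size_cv` must be >= 0")
  if (is.null(names(mean_sizes))) {
    names(mean_sizes) <- paste0("slot", seq_along(mean_sizes))
  }
  structure(list(mean_sizes = mean_sizes,
                 mean_times_min = mean_times_min,
                 time_sd = time_sd, size_cv = size_cv),
            class = "meal_protocol")
}

#' Meal-announcement behaviour model
#'
#' Models imperfect user engagement with a hybrid closed-loop system: on
#' average `skip_per_week` announcements are skipped and `delay_per_week`
#' delayed per week, and announced carbohydrate counts carry a uniform
#' relative error on `carb_error` (biased towards underestimation).
#'
#' @param skip_per_week Expected skipped announcements per week.
#' @param delay_per_week Expected delayed announcements per week.
#' @param delay_range_min Range (min) of the uniform announcement delay after
#'   meal onset for delayed announcements.
#' @param carb_error Lower/upper bound of the uniform relative carbohydrate
#'   counting error.
#' @return A `behaviour_params` list.
#' @export
behaviour_params <- function(skip_per_week = 2.5,
                             delay_per_week = 2,
                             delay_range_min = c(15, 60),
                             carb_error = c(-0.30, 0.10)) {
  if (skip_per_week < 0 || delay_per_week < 0) abort("rates must be >= 0")
  if (carb_error[1] > carb_error[2]) {
    abort("`carb_error` lower bound must not exceed upper bound")
  }
  structure(list(skip_per_week = skip_per_week,
                 delay_per_week = delay_per_week,
                 delay_range_min = delay_range_min,
                 carb_error = carb_error),
            class = "behaviour_params")
}

#' Physiological parameters of a simulated subject
#'
#' Parameters of the surrogate type 1 diabetes model used by
#' [simulate_subject()]: a minimal-model glucose compartment driven by a
#' two-compartment gut absorption chain (time-to-peak `carb_absorption_time`)
#' and a two-compartment subcutaneous insulin absorption chain (time-to-peak
#' `insulin_action_time`).  Insulin sensitivity varies sinusoidally over the
#' day (amplitude `si_sin_amplitude` of the base value) and insulin absorption
#' is scaled by a per-day multiplier drawn uniformly from
#' `1 +/- insulin_absorption_var`.
#'
#' @param basal_rate Nominal basal insulin rate (U/h) that holds the subject
#'   at `setpoint` in the fasting state.
#' @param insulin_sensitivity Glucose drop per unit of insulin action
#'   ((mg/dL)/U).
#' @param carb_ratio Insulin-to-carbohydrate ratio (g/U) used by the bolus
#'   calculator.
#' @param glucose_effectiveness Fractional self-correction rate of glucose
#'   (1/min).
#' @param carb_gain Glucose rise per gram of absorbed carbohydrate
#'   ((mg/dL)/g).
#' @param insulin_action_time Time constant of each subcutaneous insulin
#'   compartment (min); insulin action on an impulse peaks at this time.
#' @param carb_absorption_time Time constant of each gut compartment (min).
#' @param setpoint Fasting equilibrium glucose under the nominal basal
#'   (mg/dL).
#' @param si_sin_amplitude Amplitude of the sinusoidal insulin-sensitivity
#'   modulation, as a fraction of the base sensitivity (in `[0, 1)`).
#' @param si_sin_period_h,si_sin_phase_h Period and phase (hours) of the
#'   sensitivity sinusoid.
#' @param insulin_absorption_var Half-width of the uniform per-day insulin
#'   absorption multiplier (fraction, in `[0, 1)`).
#' @param cgm_noise_sd Stationary standard deviation of CGM sensor noise
#'   (mg/dL).
#' @param cgm_noise_ar Lag-1 autocorrelation of CGM sensor noise.
#' @return A `subject_params` list.
#' @export
subject_params <- function(basal_rate = 1.0,
                           insulin_sensitivity = 50,
                           carb_ratio = 12,
                           glucose_effectiveness = 0.005,
                           carb_gain = 4,
                           insulin_action_time = 55,
                           carb_absorption_time = 40,
                           setpoint = 120,
                           si_sin_amplitude = 0.30,
                           si_sin_period_h = 24,
                           si_sin_phase_h = 0,
                           insulin_absorption_var = 0.30,
                           cgm_noise_sd = 7,
                           cgm_noise_ar = 0.7) {
  pos <- c(basal_rate = basal_rate, insulin_sensitivity = insulin_sensitivity,
           carb_ratio = carb_ratio,
           glucose_effectiveness = glucose_effectiveness,
           carb_gain = carb_gain,
           insulin_action_time = insulin_action_time,
           carb_absorption_time = carb_absorption_time, setpoint = setpoint,
           si_sin_period_h = si_sin_period_h)
  if (any(pos <= 0)) {
    abort(sprintf("all rates and times must be strictly positive (%s)",
                  paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (si_sin_amplitude < 0 || si_sin_amplitude >= 1) {
    abort("`si_sin_amplitude` must be in [0, 1)")
  }
  if (insulin_absorption_var < 0 || insulin_absorption_var >= 1) {
    abort("`insulin_absorption_var` must be in [0, 1)")
  }
  if (cgm_noise_sd < 0 || abs(cgm_noise_ar) >= 1) {
    abort("`cgm_noise_sd` must be >= 0 and |`cgm_noise_ar`| < 1")
  }
  fields <- names(formals(subject_params))
  structure(mget(fields, envir = environment()), class = "subject_params")
}

#' Sample a multi-day meal and announcement scenario
#'
#' Draws one meal per protocol slot per day.  Onsets are the slot means plus
#' Gaussian jitter (`time_sd`); a day is resampled if jitter would reorder its
#' meals.  Sizes are Gaussian with the protocol's coefficient of variation,
#' truncated positive.  Announcement behaviour (skips, delays, carbohydrate
#' counting error) is sampled per event so that the weekly expectations match
#' `behaviour`.
#'
#' @param protocol A [meal_protocol()].
#' @param behaviour A [behaviour_params()].
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; the same seed reproduces the event list exactly.
#' @return A `meal_events` tibble with columns `day`, `slot`, `onset_min`,
#'   `true_g`, `announced_g`, `announce_min` (the latter two `NA` for skipped
#'   announcements).  Times are minutes from scenario start.
#' @export
sample_scenario <- function(protocol = meal_protocol(),
                            behaviour = behaviour_params(),
                            days,
                            seed = 1L) {
  if (!is.numeric(days) || length(days) != 1L || days < 1) {
    abort("`days` must be a positive number of days")
  }
  days <- as.integer(days)
  n_slot <- length(protocol$mean_sizes)
  events_per_week <- 7 * n_slot
  p_skip <- min(1, behaviour$skip_per_week / events_per_week)
  # skipped events cannot also be delayed; rescale so the weekly expectation
  # of delays still matches
  p_delay <- if (p_skip < 1) {
    min(1, (behaviour$delay_per_week / events_per_week) / (1 - p_skip))
  } else {
    0
  }

  with_seed(seed, {
    rows <- vector("list", days)
    for (d in seq_len(days)) {
      repeat {
        onsets <- protocol$mean_times_min +
          stats::rnorm(n_slot, 0, protocol$time_sd)
        if (!is.unsorted(onsets, strictly = TRUE) &&
            onsets[1] >= 0 && onsets[n_slot] <= 1435) {
          break
        }
      }
      sizes <- numeric(n_slot)
      for (j in seq_len(n_slot)) {
        repeat {
          sizes[j] <- stats::rnorm(1, protocol$mean_sizes[j],
                                   protocol$size_cv * protocol$mean_sizes[j])
          if (sizes[j] > 0) break
        }
      }
      skipped <- stats::runif(n_slot) < p_skip
      delayed <- !skipped & stats::runif(n_slot) < p_delay
      announce <- (d - 1) * 1440 + onsets
      announce[delayed] <- announce[delayed] +
        stats::runif(sum(delayed), behaviour$delay_range_min[1],
                     behaviour$delay_range_min[2])
      announce[skipped] <- NA_real_
      err <- stats::runif(n_slot, behaviour$carb_error[1],
                          behaviour$carb_error[2])
      announced_g <- ifelse(skipped, NA_real_, sizes * (1 + err))
      rows[[d]] <- tibble(
        day = d,
        slot = names(protocol$mean_sizes),
        onset_min = (d - 1) * 1440 + onsets,
        true_g = sizes,
        announced_g = announced_g,
        announce_min = announce
      )
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("meal_events", class(out))
    out
  })
}
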