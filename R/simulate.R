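#' Autocorrelated CGM sensor noise
#'
#' Adds AR(1) noise with stationary standard deviation `sd` and lag-1
#' autocorrelation `ar_coeff` to a true glucose series, emulating the
#' coloured error of subcutaneous glucose sensors.
#'
#' @param true True glucose series (mg/dL).
#' @param sd Stationary noise standard deviation (mg/dL); `0` returns the
#'   input unchanged.
#' @param ar_coeff AR(1) coefficient, `|ar_coeff| < 1`.
#' @param seed Integer seed.
#' @return Numeric series of the same length.
#' @export
cgm_noise <- function(true, sd = 7, ar_coeff = 0.7, seed = 1L) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (abs(ar_coeff) >= 1) abort("`ar_coeff` must satisfy |ar_coeff| < 1")
  if (sd == 0 || length(true) == 0) return(true)
  with_seed(seed, {
    n <- length(true)
    innov <- stats::rnorm(n, 0, sd * sqrt(1 - ar_coeff^2))
    e <- as.numeric(stats::filter(innov, ar_coeff, method = "recursive",
                                  init = stats::rnorm(1, 0, sd)))
    true + e
  })
}

# Right-hand side of the surrogate glucose-insulin model.
# State: S1, S2 (subcutaneous insulin, U), Q1, Q2 (gut carbs, g),
# G (plasma glucose, mg/dL).  u_min is insulin infusion (U/min), si_eff the
# effective insulin sensitivity at this instant ((mg/dL)/U at the setpoint).
# As in the minimal model, insulin-mediated uptake is proportional to the
# glucose level itself (-X*G), so utilisation vanishes as glucose falls and
# the trajectory cannot cross zero.
glucose_deriv <- function(state, u_min, si_eff, p, g_phys) {
  r_i <- state[2] / p$insulin_action_time      # insulin action input, U/min
  r_c <- state[4] / p$carb_absorption_time     # carb appearance, g/min
  c(u_min - state[1] / p$insulin_action_time,
    (state[1] - state[2]) / p$insulin_action_time,
    -state[3] / p$carb_absorption_time,
    (state[3] - state[4]) / p$carb_absorption_time,
    -p$glucose_effectiveness * (state[5] - g_phys) -
      si_eff * r_i * (state[5] / p$setpoint) + p$carb_gain * r_c)
}

# classic fixed-step RK4 over dt minutes (si evaluated at the step midpoint
# for the k2/k3 stages via the caller-supplied values)
rk4_step <- function(state, dt, u_min, si0, si_mid, si1, p, g_phys) {
  k1 <- glucose_deriv(state, u_min, si0, p, g_phys)
  k2 <- glucose_deriv(state + dt / 2 * k1, u_min, si_mid, p, g_phys)
  k3 <- glucose_deriv(state + dt / 2 * k2, u_min, si_mid, p, g_phys)
  k4 <- glucose_deriv(state + dt * k3, u_min, si1, p, g_phys)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate a subject's glucose, insulin and meal timeline
#'
#' Integrates the surrogate type 1 diabetes model at a 1-min internal step
#' (classic RK4), sampled every 5 min: a minimal-model glucose compartment,
#' two-compartment gut absorption, two-compartment subcutaneous insulin
#' absorption, sinusoidal intra-day insulin sensitivity, a per-day insulin
#' absorption multiplier drawn uniformly from `1 +/- insulin_absorption_var`,
#' and an AR(1) CGM noise channel.
#'
#' Insulin delivery is commanded by `dosing`, a function
#' `function(step, cgm)` called once per 5-min step with the 1-based step
#' index and the CGM samples observed so far (including the current one); it
#' must return `c(basal_uhr, bolus_u)`.  The default holds the nominal basal
#' with no boluses.
#'
#' @param params A [subject_params()].
#' @param events A `meal_events` tibble from [sample_scenario()] (or an empty
#'   tibble for no meals).
#' @param dosing Dosing callback, see Details.
#' @param days Number of simulated days.
#' @param seed Integer seed for the noise and absorption-variability streams.
#' @return A `meal_timeline` tibble with one row per 5-min step: `time_min`,
#'   `cgm_mgdl`, `true_bg_mgdl`, `basal_uhr`, `bolus_u`, `carbs_g`,
#'   `announced_carbs_g`.
#' @export
simulate_subject <- function(params, events = NULL, dosing = NULL,
                             days = 1, seed = 1L) {
  if (!inherits(params, "subject_params")) {
    abort("`params` must be created with subject_params()")
  }
  if (days < 1) abort("`days` must be >= 1")
  days <- as.integer(days)
  n <- days * 288L
  if (is.null(dosing)) {
    base <- params$basal_rate
    dosing <- function(step, cgm) c(base, 0)
  }

  carbs <- numeric(n)
  announced <- numeric(n)
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$onset_min < 0 | events$onset_min >= n * 5)) {
      abort("meal events must fall within the simulated horizon")
    }
    idx <- pmin(n, floor(events$onset_min / 5) + 1L)
    for (k in seq_along(idx)) carbs[idx[k]] <- carbs[idx[k]] + events$true_g[k]
    ann <- events[!is.na(events$announce_min), , drop = FALSE]
    if (nrow(ann) > 0) {
      ai <- pmin(n, floor(ann$announce_min / 5) + 1L)
      for (k in seq_along(ai)) {
        announced[ai[k]] <- announced[ai[k]] + ann$announced_g[k]
      }
    }
  }

  abs_mult <- with_seed(derive_seed(seed, "absorption"), {
    stats::runif(days, 1 - params$insulin_absorption_var,
                 1 + params$insulin_absorption_var)
  })
  noise <- if (params$cgm_noise_sd > 0) {
    cgm_noise(numeric(n), params$cgm_noise_sd, params$cgm_noise_ar,
              derive_seed(seed, "cgm"))
  } else {
    numeric(n)
  }

  si_base <- params$insulin_sensitivity
  si_at <- function(t_min) {
    si_base * (1 + params$si_sin_amplitude *
                 sin(2 * pi * (t_min / 60 - params$si_sin_phase_h) /
                       params$si_sin_period_h))
  }
  u_basal_min <- params$basal_rate / 60
  g_phys <- params$setpoint +
    si_base * u_basal_min / params$glucose_effectiveness

  # fasting steady state under the nominal basal
  tau_i <- params$insulin_action_time
  state <- c(S1 = u_basal_min * tau_i, S2 = u_basal_min * tau_i,
             Q1 = 0, Q2 = 0, G = params$setpoint)

  true_bg <- numeric(n)
  cgm <- numeric(n)
  basal_rec <- numeric(n)
  bolus_rec <- numeric(n)

  for (i in seq_len(n)) {
    t_min <- (i - 1L) * 5
    true_bg[i] <- state[5]
    cgm[i] <- state[5] + noise[i]
    if (!is.finite(state[5]) || state[5] <= 0) {
      abort(sprintf("glucose diverged at step %d (t = %d min)", i, t_min))
    }
    dose <- dosing(i, cgm[seq_len(i)])
    basal_rec[i] <- max(0, dose[1])
    bolus_rec[i] <- max(0, dose[2])

    state[1] <- state[1] + bolus_rec[i]   # bolus enters the first SC depot
    state[3] <- state[3] + carbs[i]       # meal enters the gut
    mult <- abs_mult[(i - 1L) %/% 288L + 1L]
    u_min <- basal_rec[i] / 60
    for (s in 0:4) {
      t0 <- t_min + s
      state <- rk4_step(state, 1, u_min,
                        si_at(t0) * mult, si_at(t0 + 0.5) * mult,
                        si_at(t0 + 1) * mult, params, g_phys)
    }
  }

  out <- tibble(
    time_min = (seq_len(n) - 1L) * 5,
    cgm_mgdl = cgm,
    true_bg_mgdl = true_bg,
    basal_uhr = basal_rec,
    bolus_u = bolus_rec,
    carbs_g = carbs,
    announced_carbs_g = announced
  )
  class(out) <- c("meal_timeline", class(out))
  attr(out, "step_min") <- 5
  out
}
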