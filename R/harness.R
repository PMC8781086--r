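#' Controller configuration for the closed-loop harness
#'
#' A generic basal-bolus controller: a clamped proportional-derivative basal
#' modulation around `target` (the feedback layer, clamped to 0-3x the
#' nominal basal and suspended below 80 mg/dL), plus meal boluses.  Automatic
#' (detected) meal boluses are weighted by `meal_bolus_weight` and carry no
#' correction component; basal delivery is suspended for
#' `basal_suspension_min` after an automatic meal bolus.  Modes: `"NMA"`
#' (no meal announcement, feedback only), `"MD"` (feedback plus the meal
#' detection/estimation module), `"MA"` (user announcements drive unweighted
#' boluses at announcement time).
#'
#' @param carb_ratio Insulin-to-carbohydrate ratio (g/U).
#' @param correction_factor Glucose drop per unit (mg/dL)/U (feedback layer
#'   scaling).
#' @param target Feedback target glucose (mg/dL).
#' @param meal_bolus_weight Weight applied to automatic meal boluses.
#' @param basal_suspension_min Basal suspension after an automatic meal
#'   bolus (min).
#' @param mode One of `"NMA"`, `"MD"`, `"MA"`.
#' @return A `controller_config` list.
#' @export
controller_config <- function(carb_ratio = 12,
                              correction_factor = 40,
                              target = 120,
                              meal_bolus_weight = 0.5,
                              basal_suspension_min = 60,
                              mode = c("NMA", "MD", "MA")) {
  mode <- match.arg(toupper(mode[1]), c("NMA", "MD", "MA"))
  if (meal_bolus_weight < 0 || meal_bolus_weight > 1) {
    abort("`meal_bolus_weight` must lie in [0, 1]")
  }
  if (basal_suspension_min < 0) abort("`basal_suspension_min` must be >= 0")
  if (carb_ratio <= 0) abort("`carb_ratio` must be positive")
  structure(list(carb_ratio = carb_ratio,
                 correction_factor = correction_factor,
                 target = target,
                 meal_bolus_weight = meal_bolus_weight,
                 basal_suspension_min = basal_suspension_min,
                 mode = mode),
            class = "controller_config")
}

#' Meal bolus from an estimated carbohydrate size
#'
#' `weight * grams / carb_ratio`, with no correction component: automatic
#' meal boluses are deliberately conservative because the feedback layer has
#' already begun responding to the excursion and the estimate may be high.
#'
#' @param grams Carbohydrate size (g), non-negative.
#' @param config A [controller_config()].
#' @param weight Bolus weight; defaults to the config's
#'   `meal_bolus_weight`.
#' @return Bolus size in insulin units.
#' @export
meal_bolus <- function(grams, config, weight = config$meal_bolus_weight) {
  if (any(grams < 0)) abort("`grams` must be non-negative")
  weight * grams / config$carb_ratio
}

# PD feedback basal around target, clamped to [0, 3x nominal]
feedback_basal <- function(cgm, nominal, config) {
  n <- length(cgm)
  g <- cgm[n]
  if (g < 80) return(0)
  slope <- if (n >= 3) rate_of_change(cgm, window = 3) else 0
  kp <- nominal / 100
  kd <- 0.3 * nominal
  min(3 * nominal, max(0, nominal + kp * (g - config$target) + kd * slope))
}

#' Run one closed-loop simulation
#'
#' Steps the surrogate simulator at 5 min with insulin commanded by the
#' generic controller in the configured mode.  In `"MD"` mode each step
#' (once `enc_len + 4` samples of history exist) builds a forecast window
#' from the observed CGM, the commanded insulin and the estimated-meal
#' channel, advances the detector, and on a flag runs the carbohydrate
#' estimator; accepted estimates trigger a weighted meal bolus, suspend
#' basal for the configured hour and are written into the model's
#' carbohydrate input at the inferred onset.  In `"MA"` mode announcements
#' (with the behaviour model's skips, delays and counting errors) drive
#' unweighted boluses at announcement time.
#'
#' @param params A [subject_params()].
#' @param events A `meal_events` tibble for the simulated horizon.
#' @param days Simulated days.
#' @param control A [controller_config()].
#' @param bundle A `qseq2seq` bundle (required for `"MD"`).
#' @param detector A [detector_config()].
#' @param seed Integer seed passed to the simulator; runs with equal seeds
#'   share sensor noise and absorption variability across modes.
#' @return A `loop_result` list: `timeline` (the `meal_timeline`),
#'   `detections` (per-flag log tibble), `mode`.
#' @export
run_closed_loop <- function(params, events, days, control,
                            bundle = NULL, detector = detector_config(),
                            seed = 1L) {
  mode <- control$mode
  if (mode == "MD" && is.null(bundle)) {
    abort("MD mode needs a trained forecaster bundle")
  }
  n <- as.integer(days) * 288L
  nominal <- params$basal_rate

  # announcement bolus schedule (MA)
  ann_bolus <- numeric(n)
  ann_carbs <- numeric(n)
  if (mode == "MA" && nrow(events) > 0) {
    ann <- events[!is.na(events$announce_min), , drop = FALSE]
    if (nrow(ann) > 0) {
      ai <- pmin(n, floor(ann$announce_min / 5) + 1L)
      for (k in seq_len(nrow(ann))) {
        ann_bolus[ai[k]] <- ann_bolus[ai[k]] +
          meal_bolus(ann$announced_g[k], control, weight = 1)
        ann_carbs[ai[k]] <- ann_carbs[ai[k]] + ann$announced_g[k]
      }
    }
  }

  env <- new.env(parent = emptyenv())
  env$insulin_u <- numeric(n)      # delivered units per step (model input)
  env$carb_in <- ann_carbs         # model carbohydrate channel
  env$basal_cmd <- numeric(n)
  env$bolus_cmd <- numeric(n)
  env$suspend_until <- -1          # step index until which basal is 0
  env$state <- new_detection_state()
  env$log <- list()

  enc_len <- if (!is.null(bundle)) bundle$config$enc_len else 24L
  stats <- if (!is.null(bundle)) bundle$stats else NULL
  need <- enc_len + 4L

  dosing <- function(step, cgm) {
    basal <- feedback_basal(cgm, nominal, control)
    if (step <= env$suspend_until) basal <- 0
    bolus <- 0
    if (mode == "MA") bolus <- ann_bolus[step]

    if (mode == "MD" && step >= need) {
      # window targeting the present sample, from commanded channels
      rows_enc <- (step - need + 1L):(step - 4L)
      rows_dec <- (step - 3L):step
      ins <- env$insulin_u
      ins[step] <- basal * (5 / 60)   # current step: basal now commanded
      x_enc <- cbind(norm_feat(cgm[rows_enc], stats, "glucose"),
                     norm_feat(ins[rows_enc], stats, "insulin"),
                     norm_feat(env$carb_in[rows_enc], stats, "carbs"))
      x_dec <- cbind(norm_feat(ins[rows_dec], stats, "insulin"),
                     norm_feat(env$carb_in[rows_dec], stats, "carbs"))
      pred <- predict_raw(bundle, x_enc, x_dec)
      roc <- rate_of_change(cgm, window = detector$roc_window)
      t_min <- (step - 1L) * 5
      upd <- update_detector(env$state, pred[4, 3], cgm[step], roc,
                             detector, t_min)
      env$state <- upd$state
      if (upd$flag) {
        first_exceed_step <- upd$state$flag_first_exceed_min / 5 + 1L
        onset_step <- first_exceed_step - detector$persistence_n
        offset <- as.integer(step - onset_step)
        est <- estimate_meal(bundle, x_enc, x_dec, cgm[step],
                             epsilon = bundle$validation_mae,
                             onset_offset = offset)
        accepted <- !est$discarded && est$grams > 0
        if (accepted) {
          bolus <- bolus + meal_bolus(est$grams, control)
          env$suspend_until <- step +
            as.integer(control$basal_suspension_min / 5)
          env$state$last_accept_min <- t_min
          os <- min(n, max(1L, as.integer(onset_step)))
          env$carb_in[os] <- env$carb_in[os] + est$grams
        }
        env$log[[length(env$log) + 1L]] <- dplyr::bind_cols(
          tibble(flag_time_min = t_min,
                 k_at_flag = upd$state$flag_k,
                 roc_mgdl_min = roc,
                 accepted = accepted),
          est)
      }
    }

    env$basal_cmd[step] <- basal
    env$bolus_cmd[step] <- bolus
    env$insulin_u[step] <- basal * (5 / 60) + bolus
    c(basal, bolus)
  }

  timeline <- simulate_subject(params, events, dosing, days = days,
                               seed = seed)
  # in MA mode the model/announcement channel is the announced carbs; in MD
  # it is the estimated-meal channel
  if (mode %in% c("MA", "MD")) {
    timeline$announced_carbs_g <- env$carb_in
  }
  detections <- if (length(env$log)) {
    dplyr::bind_rows(env$log)
  } else {
    tibble(flag_time_min = numeric(), k_at_flag = integer(),
           roc_mgdl_min = numeric(), accepted = logical(), grams = numeric(),
           final_error = numeric(), iterations = integer(),
           capped = logical(), discarded = logical())
  }
  structure(list(timeline = timeline, detections = detections, mode = mode),
            class = "loop_result")
}

#' @export
print.loop_result <- function(x, ...) {
  cat(sprintf("<loop_result: mode %s, %d steps, %d flags (%d accepted)>\n",
              x$mode, nrow(x$timeline), nrow(x$detections),
              sum(x$detections$accepted)))
  invisible(x)
}
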