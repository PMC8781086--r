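timeline_cols <- c("time_min", "cgm_mgdl", "true_bg_mgdl", "basal_uhr",
                   "bolus_u", "carbs_g", "announced_carbs_g")
events_cols <- c("onset_min", "true_g", "announced_g", "announce_min")

#' Read and write timeline CSV files
#'
#' One row per 5-min step with columns `time_min`, `cgm_mgdl`,
#' `true_bg_mgdl`, `basal_uhr`, `bolus_u`, `carbs_g`, `announced_carbs_g`.
#' Reading validates the schema (naming the missing column) and enforces the
#' 5-min step; writing and re-reading round-trips all columns.
#'
#' @param path CSV path.
#' @param timeline A `meal_timeline` tibble.
#' @return `read_timeline()` a `meal_timeline`; `write_timeline()` the path,
#'   invisibly.
#' @export
read_timeline <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(timeline_cols, names(df))
  if (length(missing)) {
    abort(sprintf("timeline file %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  steps <- diff(df$time_min)
  if (length(steps) && any(steps != 5)) {
    bad <- which(steps != 5)[1]
    abort(sprintf("timeline step must be 5 min; row %d steps by %g", bad + 1,
                  steps[bad]))
  }
  out <- df[, timeline_cols]
  class(out) <- c("meal_timeline", class(out))
  attr(out, "step_min") <- 5
  out
}

#' @rdname read_timeline
#' @export
write_timeline <- function(timeline, path) {
  missing <- setdiff(timeline_cols, names(timeline))
  if (length(missing)) {
    abort(sprintf("timeline lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(timeline[, timeline_cols], path)
  invisible(path)
}

#' Read and write meal-event CSV files
#'
#' Columns `onset_min`, `true_g`, `announced_g`, `announce_min` (the latter
#' two empty for skipped announcements), plus `day` and `slot` when present.
#'
#' @param path CSV path.
#' @param events A `meal_events` tibble.
#' @return `read_events()` a `meal_events` tibble; `write_events()` the
#'   path, invisibly.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(events_cols, names(df))
  if (length(missing)) {
    abort(sprintf("events file %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  class(df) <- c("meal_events", class(df))
  df
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Read and write scenario configuration YAML
#'
#' A scenario file records the subject, meal-protocol and behaviour
#' parameters plus the seeds, so any run can be reproduced from its recorded
#' configuration.
#'
#' @param path YAML path.
#' @param subject A [subject_params()].
#' @param protocol A [meal_protocol()].
#' @param behaviour A [behaviour_params()].
#' @param days Scenario length in days.
#' @param seed Scenario seed.
#' @return `read_scenario()` a list with elements `subject`, `protocol`,
#'   `behaviour`, `days`, `seed`; `write_scenario()` the path, invisibly.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("subject", "protocol", "behaviour", "days", "seed")) {
    if (is.null(y[[k]])) abort(sprintf("scenario %s lacks field `%s`", path, k))
  }
  prot <- y$protocol
  list(
    subject = do.call(subject_params, y$subject),
    protocol = meal_protocol(
      mean_sizes = stats::setNames(unlist(prot$mean_sizes),
                                   names(prot$mean_sizes)),
      mean_times_min = unlist(prot$mean_times_min),
      time_sd = prot$time_sd, size_cv = prot$size_cv),
    behaviour = do.call(behaviour_params, y$behaviour),
    days = y$days,
    seed = y$seed)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(path, subject = subject_params(),
                           protocol = meal_protocol(),
                           behaviour = behaviour_params(),
                           days = 14, seed = 1L) {
  yaml::write_yaml(list(
    subject = unclass(subject),
    protocol = list(mean_sizes = as.list(protocol$mean_sizes),
                    mean_times_min = protocol$mean_times_min,
                    time_sd = protocol$time_sd, size_cv = protocol$size_cv),
    behaviour = unclass(behaviour),
    days = days, seed = seed), path)
  invisible(path)
}

#' Deterministic fixtures for tests and examples
#'
#' Writes small, fully deterministic inputs: `"steady"` (one meal-free,
#' noise-free day), `"single_meal"` (one unannounced 50 g meal at noon,
#' noise-free), `"ramp"` (a hand-built trace whose CGM ramps at 2 mg/dL/min
#' from step 30, for detector tests) or `"full_scenario"` (a 7-day scenario
#' YAML, events CSV and timeline CSV).
#'
#' @param kind One of `"steady"`, `"single_meal"`, `"ramp"`,
#'   `"full_scenario"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture <- function(kind = c("steady", "single_meal", "ramp",
                                  "full_scenario"),
                         seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  quiet <- subject_params(si_sin_amplitude = 0, insulin_absorption_var = 0,
                          cgm_noise_sd = 0)
  paths <- character()
  if (kind == "steady") {
    tl <- simulate_subject(quiet, events = NULL, days = 1, seed = seed)
    paths <- c(timeline = file.path(dir, "steady_timeline.csv"))
    write_timeline(tl, paths[["timeline"]])
  } else if (kind == "single_meal") {
    ev <- tibble(day = 1L, slot = "lunch", onset_min = 720, true_g = 50,
                 announced_g = NA_real_, announce_min = NA_real_)
    class(ev) <- c("meal_events", class(ev))
    tl <- simulate_subject(quiet, ev, days = 1, seed = seed)
    paths <- c(timeline = file.path(dir, "single_meal_timeline.csv"),
               events = file.path(dir, "single_meal_events.csv"))
    write_timeline(tl, paths[["timeline"]])
    write_events(ev, paths[["events"]])
  } else if (kind == "ramp") {
    n <- 96L
    ramp_start <- 30L
    bg <- rep(120, n)
    rise <- pmax(0, seq_len(n) - ramp_start) * 10   # 2 mg/dL/min
    bg <- pmin(bg + rise, 320)
    tl <- tibble(time_min = (seq_len(n) - 1L) * 5, cgm_mgdl = bg,
                 true_bg_mgdl = bg, basal_uhr = 1, bolus_u = 0,
                 carbs_g = 0, announced_carbs_g = 0)
    class(tl) <- c("meal_timeline", class(tl))
    paths <- c(timeline = file.path(dir, "ramp_timeline.csv"))
    write_timeline(tl, paths[["timeline"]])
  } else {
    protocol <- meal_protocol()
    behaviour <- behaviour_params()
    subject <- subject_params()
    ev <- sample_scenario(protocol, behaviour, days = 7, seed = seed)
    tl <- simulate_subject(subject, ev, days = 7, seed = seed)
    paths <- c(scenario = file.path(dir, "scenario.yaml"),
               events = file.path(dir, "events.csv"),
               timeline = file.path(dir, "timeline.csv"))
    write_scenario(paths[["scenario"]], subject, protocol, behaviour,
                   days = 7, seed = seed)
    write_events(ev, paths[["events"]])
    write_timeline(tl, paths[["timeline"]])
  }
  invisible(paths)
}
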