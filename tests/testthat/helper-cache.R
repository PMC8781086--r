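# Expensive shared objects are built once per test run and reused across
# test files.

.ms_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .ms_test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .ms_test_cache)
  }
  get(name, envir = .ms_test_cache)
}

# one subject, one simulated week in hybrid (announcement-driven) closed
# loop: the standard small training timeline
small_training_timeline <- function() {
  cached("small_timeline", {
    sp <- subject_params()
    ev <- sample_scenario(days = 7, seed = 301)
    ctl <- controller_config(mode = "MA", carb_ratio = sp$carb_ratio)
    run_closed_loop(sp, ev, days = 7, control = ctl, seed = 302)$timeline
  })
}

# quick individualised forecaster on the small timeline
small_bundle <- function() {
  cached("small_bundle", {
    cfg <- training_config(max_epochs = 12L, seed = 7L)
    pop <- train_population(small_training_timeline(), cfg)
    ft <- cfg
    ft$max_epochs <- 4L
    finetune_individual(pop, small_training_timeline(), ft)
  })
}

# a hand-built bundle whose upper head is shifted far up (never exceeded) or
# far down; used to drive the detector deterministically in harness tests
offset_bundle <- function(upper_shift) {
  params <- .ms_init_params(3L, 2L, 8L, 1L)
  params$head_b[3] <- upper_shift
  stats <- structure(list(
    offset = c(glucose = 0, insulin = 0, carbs = 0),
    scale = c(glucose = 1, insulin = 1, carbs = 1)), class = "window_stats")
  structure(list(params = params, config = training_config(lstm_cells = 8L),
                 stats = stats,
                 history = tibble::tibble(), best_epoch = 0L,
                 val_loss = NA_real_, validation_mae = 5, stage = "stub"),
            class = "qseq2seq")
}

# full desk-scale benchmark shared by the acceptance tests (trains the
# population + individual models and runs MD and NMA over held-out weeks)
acceptance_benchmark <- function() {
  cached("benchmark", {
    meal_detection_benchmark(n_subjects = 3, train_days = 21, test_days = 21,
                             seed = 101L)
  })
}
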