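test_that("an over-capacity model drives the loss of one repeated window near zero", {
  # 200 copies of one deterministic window: the network should memorise it
  n <- 28L
  tl <- tibble::tibble(
    time_min = (seq_len(n) - 1) * 5,
    cgm_mgdl = 120 + 30 * sin(seq_len(n) / 4),
    true_bg_mgdl = 120, basal_uhr = 1, bolus_u = 0,
    carbs_g = 0, announced_carbs_g = 0)
  class(tl) <- c("meal_timeline", class(tl))
  w <- build_windows(tl, enc_len = 24L)
  rep_idx <- rep(1L, 200L)
  reps <- mealsense:::subset_windows(w, rep_idx)
  cfg <- training_config(lstm_cells = 32L, max_epochs = 120L,
                         patience = 120L, pretrain_lr = 5e-3, seed = 3L)
  fit <- mealsense:::.ms_train(
    mealsense:::.ms_init_params(3L, 2L, cfg$lstm_cells, cfg$seed),
    reps$x_enc, reps$x_dec, reps$y,
    0:159, 160:199, cfg$quantiles, cfg$pretrain_lr, 64L,
    cfg$max_epochs, cfg$patience, 0, cfg$clip_norm, 1L)
  expect_lt(fit$best_val_loss, 1e-2)
})

test_that("the forecaster beats last-value-carried-forward on noise-free dynamics", {
  sp <- subject_params(si_sin_amplitude = 0, insulin_absorption_var = 0,
                       cgm_noise_sd = 0)
  ev <- sample_scenario(days = 7, seed = 21)
  ctl <- controller_config(mode = "MA", carb_ratio = sp$carb_ratio)
  tl <- run_closed_loop(sp, ev, days = 7, control = ctl, seed = 22)$timeline
  cfg <- training_config(max_epochs = 15L, seed = 5L)
  b <- train_population(tl, cfg)

  w <- build_windows(tl, cfg$enc_len, stats = b$stats)
  sp2 <- mealsense:::chrono_split(nrow(w$y), cfg$split)
  # LVCF: predict glucose at t by the last encoder value (t - 20 min)
  st <- b$stats
  lvcf <- w$x_enc[sp2$val, cfg$enc_len, 1] * st$scale[["glucose"]] +
    st$offset[["glucose"]]
  obs <- w$y[sp2$val, 4] * st$scale[["glucose"]] + st$offset[["glucose"]]
  lvcf_mae <- mean(abs(lvcf - obs))
  expect_lt(b$validation_mae, lvcf_mae)
})

test_that("training is deterministic under a fixed seed", {
  tl <- small_training_timeline()
  cfg <- training_config(max_epochs = 3L, seed = 17L)
  a <- train_population(tl, cfg)
  b <- train_population(tl, cfg)
  expect_identical(a$val_loss, b$val_loss)
  expect_identical(a$params$enc_W, b$params$enc_W)
})

test_that("zero-epoch fine-tuning keeps weights and refreshes the validation MAE", {
  pop <- small_bundle()
  cfg <- pop$config
  cfg$max_epochs <- 0L
  ft <- finetune_individual(pop, small_training_timeline(), cfg)
  expect_identical(ft$params, pop$params)
  expect_identical(ft$stats, pop$stats)   # frozen normalisation statistics
  expect_true(is.finite(ft$validation_mae))
})

test_that("fine-tuning does not hurt the individual validation loss", {
  pop <- cached("pop_for_ft", {
    train_population(small_training_timeline(),
                     training_config(max_epochs = 10L, seed = 7L))
  })
  cfg <- pop$config
  cfg$max_epochs <- 5L
  ft <- finetune_individual(pop, small_training_timeline(), cfg)
  expect_lte(ft$val_loss, pop$val_loss + 1e-6)
  expect_identical(ft$stats, pop$stats)
})

test_that("predictions are pure functions of the window and well shaped", {
  b <- small_bundle()
  tl <- small_training_timeline()
  w <- build_windows(tl, b$config$enc_len, stats = b$stats)
  sub <- mealsense:::subset_windows(w, c(10L, 10L, 25L))
  pq <- predict_quantiles(b, sub)
  expect_equal(nrow(pq), 3 * 4)
  w1 <- dplyr::filter(pq, window == 1)
  w2 <- dplyr::filter(pq, window == 2)
  expect_equal(w1[, c("lower", "median", "upper")],
               w2[, c("lower", "median", "upper")])
  expect_true(all(is.finite(pq$median)))
  # quantile crossing is rare on trained models
  crossed <- mean(pq$upper < pq$lower)
  expect_lt(crossed, 0.05)
})

test_that("epsilon is the mean absolute validation error", {
  expect_equal(compute_epsilon(c(100, 110), c(90, 120)), 10)
  expect_equal(compute_epsilon(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(31)
  y <- stats::rnorm(100)
  yh <- stats::rnorm(100)
  expect_equal(compute_epsilon(y, yh), mean(abs(y - yh)), tolerance = 1e-12)
  expect_error(compute_epsilon(numeric(0), numeric(0)), "non-empty")
  expect_error(compute_epsilon(1:3, 1:2), "equal-length")
})

test_that("tidy and glance summarise a fitted bundle", {
  b <- small_bundle()
  td <- tidy(b)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(td)))
  g <- glance(b)
  expect_equal(nrow(g), 1L)
  expect_equal(g$lstm_cells, 64L)
  expect_gt(g$n_params, 30000)
})
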