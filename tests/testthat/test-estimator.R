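# A stub error function emulating a forecaster whose median response is
# monotone in the injected meal size: the error decreases linearly to a
# minimum at `m_opt` then rises again.
stub_error <- function(m_opt, slope_down = 1, slope_up = 1, floor = 0) {
  function(g) {
    if (g <= m_opt) floor + slope_down * (m_opt - g)
    else floor + slope_up * (g - m_opt)
  }
}

# exhaustive 1-g grid oracle: the smallest grams in 0..90 meeting epsilon
grid_oracle <- function(error_fn, epsilon) {
  for (g in 0:90) if (error_fn(g) <= epsilon) return(g)
  NA_integer_
}

test_that("dynamics verification discards non-responding candidates", {
  expect_true(verify_dynamics(c(40, 28, 15)))
  expect_false(verify_dynamics(c(40, 41, 43)))
  expect_false(verify_dynamics(c(40, 40)))
  expect_error(verify_dynamics(40), "at least two")
})

test_that("the coarse/fine search recovers a 34-g meal through the documented walk", {
  calls <- numeric(0)
  fn <- function(g) {
    calls <<- c(calls, g)
    stub_error(34, slope_down = 1, slope_up = 0.05)(g)
  }
  res <- mealsense:::meal_search(fn, epsilon = 0.7)
  expect_equal(res$grams, 34)
  expect_false(res$capped)
  expect_false(res$discarded)
  # coarse ascends 10..40, fine re-runs from 30 upward
  expect_equal(calls, c(0, 10, 20, 30, 40, 31, 32, 33, 34))
})

test_that("search agrees with the exhaustive grid oracle on randomized monotone stubs", {
  set.seed(71)
  for (rep in seq_len(120)) {
    m_opt <- sample(0:90, 1)
    epsilon <- stats::runif(1, 0.3, 8)
    # post-optimum slope gentle relative to epsilon so the error keeps
    # falling through the threshold at the coarse resolution
    fn <- stub_error(m_opt,
                     slope_down = stats::runif(1, 0.5, 3),
                     slope_up = stats::runif(1, 0.001, epsilon / 10))
    res <- mealsense:::meal_search(fn, epsilon)
    expect_false(res$discarded)
    expect_equal(res$grams, grid_oracle(fn, epsilon))
    expect_lte(res$iterations, 19)
  }
})

test_that("inexplicable deviations cap at 90 g", {
  # error decreases with grams but never reaches the threshold
  fn <- function(g) 500 - g
  res <- mealsense:::meal_search(fn, epsilon = 1)
  expect_equal(res$grams, 90)
  expect_true(res$capped)
  expect_false(res$discarded)
})

test_that("a forecaster insensitive to the meal input is discarded", {
  fn <- function(g) 42
  res <- mealsense:::meal_search(fn, epsilon = 1)
  expect_true(res$discarded)
  expect_equal(res$grams, 0)
  res2 <- mealsense:::meal_search(function(g) 42 + g / 10, epsilon = 1)
  expect_true(res2$discarded)
})

test_that("degenerate thresholds are rejected", {
  expect_error(mealsense:::meal_search(stub_error(30), epsilon = 0),
               "positive")
  expect_error(mealsense:::meal_search(stub_error(30), epsilon = -2),
               "positive")
})

test_that("estimate_meal on a trained bundle returns admissible results", {
  b <- small_bundle()
  tl <- small_training_timeline()
  w <- build_windows(tl, b$config$enc_len, stats = b$stats)
  i <- 500L
  x_enc <- matrix(w$x_enc[i, , ], ncol = 3)
  x_dec <- matrix(w$x_dec[i, , ], ncol = 2)
  obs <- w$y[i, 4] * b$stats$scale[["glucose"]] + b$stats$offset[["glucose"]]
  res <- estimate_meal(b, x_enc, x_dec, cgm_now = obs + 40,
                       epsilon = b$validation_mae, onset_offset = 6L)
  expect_gte(res$grams, 0)
  expect_lte(res$grams, 90)
  expect_lte(res$iterations, 19)
  if (res$discarded) expect_equal(res$grams, 0)
})
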