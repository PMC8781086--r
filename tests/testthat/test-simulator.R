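quiet_subject <- function(...) {
  subject_params(si_sin_amplitude = 0, insulin_absorption_var = 0,
                 cgm_noise_sd = 0, ...)
}

test_that("fasting subject under nominal basal holds the setpoint", {
  tl <- simulate_subject(quiet_subject(), events = NULL, days = 2, seed = 1)
  after_burnin <- tl$true_bg_mgdl[tl$time_min >= 120]
  expect_true(all(abs(after_burnin - 120) < 2))
  expect_equal(tl$cgm_mgdl, tl$true_bg_mgdl)  # no sensor noise
})

test_that("an unbolused meal produces a monotone rise then a peak and decline", {
  ev <- tibble::tibble(day = 1L, slot = "lunch", onset_min = 720,
                       true_g = 50, announced_g = NA_real_,
                       announce_min = NA_real_)
  tl <- simulate_subject(quiet_subject(), ev, days = 1, seed = 1)
  g <- tl$true_bg_mgdl
  onset_idx <- 720 / 5 + 1
  # strictly rising for at least 20 min after onset
  expect_true(all(diff(g[onset_idx + 1:5]) > 0))
  peak <- which.max(g)
  expect_gt(peak, onset_idx + 4)
  # declines after the peak
  expect_true(all(diff(g[peak:(peak + 12)]) < 0))
  expect_gt(max(g), 180)  # a 50 g unbolused meal is a real excursion
})

test_that("trajectory agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- quiet_subject()
  ev <- tibble::tibble(day = 1L, slot = "lunch", onset_min = 0, true_g = 50,
                       announced_g = NA_real_, announce_min = NA_real_)
  tl <- simulate_subject(p, ev, days = 1, seed = 1)

  u <- p$basal_rate / 60
  tau <- p$insulin_action_time
  rhs <- function(t, y, parms) {
    ri <- y[2] / tau
    rc <- y[4] / p$carb_absorption_time
    gphys <- p$setpoint + p$insulin_sensitivity * u / p$glucose_effectiveness
    list(c(u - y[1] / tau,
           (y[1] - y[2]) / tau,
           -y[3] / p$carb_absorption_time,
           (y[3] - y[4]) / p$carb_absorption_time,
           -p$glucose_effectiveness * (y[5] - gphys) -
             p$insulin_sensitivity * ri * (y[5] / p$setpoint) +
             p$carb_gain * rc))
  }
  y0 <- c(u * tau, u * tau, 50, 0, 120)
  sol <- deSolve::lsoda(y0, times = seq(0, 1435, by = 5), func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-8)
  expect_lt(max(abs(sol[, 6] - tl$true_bg_mgdl)), 0.5)
})

test_that("simulation is deterministic and physically admissible", {
  sp <- subject_params()
  ev <- sample_scenario(days = 3, seed = 4)
  a <- simulate_subject(sp, ev, days = 3, seed = 11)
  b <- simulate_subject(sp, ev, days = 3, seed = 11)
  expect_identical(a, b)
  c <- simulate_subject(sp, ev, days = 3, seed = 12)
  expect_false(identical(a$cgm_mgdl, c$cgm_mgdl))

  expect_true(all(a$basal_uhr >= 0))
  expect_true(all(a$bolus_u >= 0))
  expect_true(all(a$true_bg_mgdl > 0))
})

test_that("events outside the simulated horizon are rejected", {
  ev <- tibble::tibble(day = 9L, slot = "lunch", onset_min = 3000,
                       true_g = 50, announced_g = NA_real_,
                       announce_min = NA_real_)
  expect_error(simulate_subject(quiet_subject(), ev, days = 1, seed = 1),
               "horizon")
})

test_that("cgm noise has the requested stationary SD and is reproducible", {
  x <- rep(120, 10000)
  y <- cgm_noise(x, sd = 7, ar_coeff = 0.7, seed = 3)
  e <- y - x
  expect_lt(abs(stats::sd(e) - 7) / 7, 0.10)
  # lag-1 autocorrelation near the AR coefficient
  expect_lt(abs(stats::cor(e[-1], e[-length(e)]) - 0.7), 0.05)

  expect_identical(y, cgm_noise(x, 7, 0.7, seed = 3))
  expect_identical(cgm_noise(x, 0, 0.7, seed = 3), x)
  expect_error(cgm_noise(x, sd = -1), ">= 0")
  expect_error(cgm_noise(x, sd = 1, ar_coeff = 1), "ar_coeff")
})
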