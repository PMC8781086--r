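test_that("meal boluses follow the weighted insulin-to-carb rule with no correction", {
  ctl <- controller_config(carb_ratio = 10)
  expect_equal(meal_bolus(60, ctl), 3.0)
  expect_equal(meal_bolus(0, ctl), 0)
  expect_equal(meal_bolus(60, ctl, weight = 1), 6.0)
  expect_error(meal_bolus(-5, ctl), "non-negative")
})

test_that("an MD run that never flags delivers exactly the NMA insulin", {
  sp <- subject_params()
  ev <- sample_scenario(days = 2, seed = 51)
  # stub forecaster whose upper bound sits far above any plausible CGM
  never <- offset_bundle(upper_shift = 1e4)
  nma <- run_closed_loop(sp, ev, days = 2,
                         control = controller_config(mode = "NMA"),
                         seed = 52)
  md <- run_closed_loop(sp, ev, days = 2,
                        control = controller_config(mode = "MD"),
                        bundle = never, seed = 52)
  expect_equal(nrow(md$detections), 0L)
  expect_identical(md$timeline$basal_uhr, nma$timeline$basal_uhr)
  expect_identical(md$timeline$bolus_u, nma$timeline$bolus_u)
  expect_identical(md$timeline$cgm_mgdl, nma$timeline$cgm_mgdl)
})

test_that("MD meal boluses suspend basal for exactly 12 five-minute steps", {
  bm <- acceptance_benchmark()
  run <- bm$md$runs[[1]]
  tl <- run$timeline
  bolus_steps <- which(tl$bolus_u > 0)
  expect_gt(length(bolus_steps), 5)
  for (s in bolus_steps) {
    # ignore boluses whose suspension window merges with a later one
    later <- bolus_steps[bolus_steps > s & bolus_steps <= s + 12]
    if (length(later) || s + 12 > nrow(tl)) next
    expect_equal(tl$basal_uhr[s + 1:12], rep(0, 12))
  }
})

test_that("MD boluses occur only at accepted flag times and insulin is never negative", {
  bm <- acceptance_benchmark()
  for (run in bm$md$runs) {
    tl <- run$timeline
    expect_true(all(tl$basal_uhr >= 0))
    expect_true(all(tl$bolus_u >= 0))
    bolus_min <- tl$time_min[tl$bolus_u > 0]
    accepted <- run$detections$flag_time_min[run$detections$accepted]
    expect_setequal(bolus_min, accepted)
  }
})

test_that("MA with perfect behaviour announces every meal at onset with true grams", {
  sp <- subject_params()
  prot <- meal_protocol()
  perfect <- behaviour_params(skip_per_week = 0, delay_per_week = 0,
                              carb_error = c(0, 0))
  ev <- sample_scenario(prot, perfect, days = 3, seed = 61)
  expect_true(all(!is.na(ev$announce_min)))
  expect_equal(ev$announce_min, ev$onset_min)
  expect_equal(ev$announced_g, ev$true_g)

  ctl <- controller_config(mode = "MA", carb_ratio = sp$carb_ratio)
  run <- run_closed_loop(sp, ev, days = 3, control = ctl, seed = 62)
  tl <- run$timeline
  onset_steps <- floor(ev$onset_min / 5) + 1
  expect_equal(sort(which(tl$bolus_u > 0)), sort(unique(onset_steps)))
  expect_equal(sum(tl$bolus_u), sum(ev$true_g / sp$carb_ratio))
})

test_that("loop summaries expose mode, flags and glycaemic metrics", {
  bm <- acceptance_benchmark()
  g <- glance(bm$md$runs[[1]])
  expect_equal(g$mode, "MD")
  expect_equal(g$tir + g$tar + g$tbr, 100, tolerance = 1e-9)
  expect_gt(g$total_insulin_u, 0)
})
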