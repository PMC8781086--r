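meals_at <- function(onsets, slot = NA_character_) {
  tibble::tibble(onset_min = onsets, slot = slot)
}
dets_at <- function(times) tibble::tibble(flag_time_min = times)

test_that("matching applies the 120-min true-positive window", {
  m <- match_events(meals_at(c(420, 780)), dets_at(c(455, 1300)))
  expect_equal(m$tp, 1L)
  expect_equal(m$fn, 1L)
  expect_equal(m$fp, 1L)
  expect_equal(m$delays, 35)

  m2 <- match_events(meals_at(600), dets_at(730))   # 130 min late
  expect_equal(c(m2$tp, m2$fn, m2$fp), c(0L, 1L, 1L))

  m3 <- match_events(meals_at(c(100, 500)), dets_at(numeric(0)))
  expect_equal(c(m3$tp, m3$fn, m3$fp), c(0L, 2L, 0L))
})

# brute-force maximum bipartite matching by recursion (instances <= 8 x 8)
optimal_tp <- function(onsets, flags, max_delay = 120) {
  best <- 0L
  recurse <- function(fi, used) {
    if (fi > length(flags)) {
      best <<- max(best, sum(used))
      return()
    }
    recurse(fi + 1L, used)   # leave this detection unmatched
    for (j in seq_along(onsets)) {
      d <- flags[fi] - onsets[j]
      if (!used[j] && d > 0 && d <= max_delay) {
        used[j] <- TRUE
        recurse(fi + 1L, used)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(onsets)))
  best
}

test_that("greedy matching never exceeds and usually attains the optimal TP count", {
  set.seed(91)
  n_equal <- 0L
  for (rep in 1:40) {
    onsets <- sort(stats::runif(sample(2:6, 1), 0, 2000))
    flags <- sort(stats::runif(sample(2:6, 1), 0, 2100))
    m <- match_events(meals_at(onsets), dets_at(flags))
    opt <- optimal_tp(onsets, flags)
    expect_lte(m$tp, opt)
    if (m$tp == opt) n_equal <- n_equal + 1L
    # counts always reconcile
    expect_equal(m$tp + m$fn, length(onsets))
    expect_equal(m$tp + m$fp, length(flags))
    expect_true(all(m$delays > 0 & m$delays <= 120))
  }
  expect_gte(n_equal, 35)   # greedy is the documented tie-break
})

test_that("precision, recall and F-score follow their defining arithmetic", {
  m <- list(tp = 9, fp = 1, fn = 3)
  expect_equal(precision(m), 90)
  expect_equal(recall(m), 75)
  expect_equal(fscore(m), 2 * 0.9 * 0.75 / (0.9 + 0.75), tolerance = 1e-12)

  perfect <- list(tp = 10, fp = 0, fn = 0)
  expect_equal(precision(perfect), 100)
  expect_equal(recall(perfect), 100)
  expect_equal(fscore(perfect), 1)

  # 92% / 92% gives F = 0.92 exactly
  m92 <- list(tp = 23, fp = 2, fn = 2)
  expect_equal(precision(m92), 92)
  expect_equal(recall(m92), 92)
  expect_equal(fscore(m92), 0.92)

  expect_error(precision(list(tp = 0, fp = 0, fn = 1)), "undefined")
  expect_error(recall(list(tp = 0, fp = 1, fn = 0)), "undefined")
})

test_that("F-score reconstructs from published precision/recall pairs", {
  f <- function(p, r) fscore(list(tp = p * r, fp = (100 - p) * r,
                                  fn = p * (100 - r)))
  expect_equal(f(92.5, 82), 0.869, tolerance = 5e-4)
  expect_equal(f(93, 88), 0.904, tolerance = 5e-4)
  expect_equal(f(84, 76), 0.798, tolerance = 5e-4)
  expect_equal(f(92, 92), 0.92, tolerance = 1e-12)
})

test_that("glycaemic summary partitions time exactly", {
  s <- glycaemic_summary(rep(100, 50))
  expect_equal(c(s$tir, s$tar, s$tbr, s$mean_bg), c(100, 0, 0, 100))

  s2 <- glycaemic_summary(c(rep(100, 10), rep(200, 10)))
  expect_equal(c(s2$tir, s2$tar), c(50, 50))

  s3 <- glycaemic_summary(rep(70, 5))
  expect_equal(s3$tbr, 100)
  s4 <- glycaemic_summary(rep(180, 5))
  expect_equal(s4$tar, 100)   # 180 counts as above range

  set.seed(41)
  bg <- stats::runif(500, 40, 400)
  s5 <- glycaemic_summary(bg)
  expect_equal(s5$tir + s5$tar + s5$tbr, 100, tolerance = 1e-9)
  expect_error(glycaemic_summary(numeric(0)), "non-empty")
  expect_error(glycaemic_summary(c(100, -5)), "positive")
})

test_that("risk indices vanish at the symmetrisation root and split by sign", {
  r <- risk_indices(rep(112.5, 10))
  expect_lt(abs(r$lbgi), 1e-3)
  expect_lt(abs(r$hbgi), 1e-3)

  lo <- risk_indices(rep(50, 10))
  expect_equal(lo$hbgi, 0)
  expect_gt(lo$lbgi, 0)
  hi <- risk_indices(rep(300, 10))
  expect_equal(hi$lbgi, 0)
  expect_gt(hi$hbgi, 0)

  set.seed(42)
  bg <- stats::runif(200, 40, 400)
  r2 <- risk_indices(bg)
  expect_equal(r2$ri, r2$lbgi + r2$hbgi, tolerance = 1e-12)
})

test_that("CVGA assigns the documented zones and clamps the axes", {
  expect_equal(as.character(cvga_point(rep(110, 5))$zone), "A")
  expect_equal(as.character(cvga_zone(95, 250)), "UpperB")
  expect_equal(as.character(cvga_zone(55, 170)), "LowerC")
  expect_equal(as.character(cvga_zone(55, 250)), "LowerD")
  expect_equal(as.character(cvga_zone(80, 350)), "UpperD")
  expect_equal(as.character(cvga_zone(60, 350)), "E")

  p <- cvga_point(c(30, 500))
  expect_equal(c(p$min_bg, p$max_bg), c(50, 400))
  expect_equal(as.character(p$zone), "E")
})

test_that("CVGA zones degrade monotonically as control worsens", {
  band <- function(z) {
    chartr("ABCDE", "12345",
           sub("Upper|Lower", "", as.character(z)))
  }
  mins <- c(110, 95, 90, 85, 70, 65, 50)
  maxs <- c(110, 150, 180, 250, 300, 350, 400)
  for (mx in maxs) {
    zones <- band(cvga_zone(mins, rep(mx, length(mins))))
    expect_true(!is.unsorted(zones))   # worsening min never improves
  }
  for (mn in mins) {
    zones <- band(cvga_zone(rep(mn, length(maxs)), maxs))
    expect_true(!is.unsorted(zones))   # worsening max never improves
  }
})

test_that("paired comparison gates on normality and applies Bonferroni", {
  set.seed(7)
  a <- stats::rnorm(12, 100, 5)
  res <- paired_compare(a, a + 8 + stats::rnorm(12, 0, 1))
  expect_equal(res$test, "paired t-test")
  expect_lt(res$p_value, 0.05)

  skewed <- a + stats::rlnorm(12, 0, 1.5)
  res2 <- paired_compare(a, skewed)
  expect_equal(res2$test, "Wilcoxon signed-rank")

  res3 <- paired_compare(a, a + 1 + stats::rnorm(12, 0, 0.3),
                         n_comparisons = 2)
  expect_equal(res3$alpha, 0.025)
  expect_error(paired_compare(a, a), "zero")
  expect_error(paired_compare(a, a + 2), "constant")
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
})
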