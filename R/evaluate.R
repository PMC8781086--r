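#' Match detections to true meals
#'
#' Greedy chronological one-to-one matching: walking through detections in
#' time order, each detection claims the most recent still-unmatched meal
#' whose onset precedes it by at most `max_delay` minutes.  Matched
#' detections are true positives, unmatched detections false positives and
#' unmatched meals false negatives.
#'
#' @param true_meals A `meal_events` tibble (or any tibble with `onset_min`,
#'   optionally `slot`), time-sorted.
#' @param detections A tibble with `flag_time_min` (e.g. the `detections`
#'   log of a [run_closed_loop()] result), time-sorted.
#' @param max_delay Maximum detection delay counted as a true positive (min).
#' @return A `match_result` list: counts `tp`, `fp`, `fn`, a `delays` vector
#'   (min, one per true positive) and a `matches` tibble (`flag_time_min`,
#'   `onset_min`, `slot`, `delay_min`).
#' @export
match_events <- function(true_meals, detections, max_delay = 120) {
  onsets <- sort(true_meals$onset_min)
  slots <- if ("slot" %in% names(true_meals)) {
    true_meals$slot[order(true_meals$onset_min)]
  } else {
    rep(NA_character_, length(onsets))
  }
  flags <- sort(detections$flag_time_min)
  taken <- logical(length(onsets))
  rows <- list()
  fp <- 0L
  for (ft in flags) {
    delay <- ft - onsets
    ok <- which(!taken & delay > 0 & delay <= max_delay)
    if (length(ok) == 0) {
      fp <- fp + 1L
    } else {
      j <- ok[which.max(onsets[ok])]   # most recent eligible meal
      taken[j] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        flag_time_min = ft, onset_min = onsets[j], slot = slots[j],
        delay_min = ft - onsets[j])
    }
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(flag_time_min = numeric(), onset_min = numeric(),
           slot = character(), delay_min = numeric())
  }
  structure(list(tp = nrow(matches), fp = fp,
                 fn = length(onsets) - nrow(matches),
                 delays = matches$delay_min, matches = matches),
            class = "match_result")
}

#' Detection precision, recall and F-score
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, in percent;
#' the F-score is their harmonic mean `2PR / (P + R)` as a fraction.  A zero
#' denominator is an undefined value and raises an error rather than
#' silently returning zero.
#'
#' @param m A `match_result` from [match_events()], or a list with `tp`,
#'   `fp`, `fn` counts.
#' @return A percentage (`precision`, `recall`) or fraction (`fscore`).
#' @export
precision <- function(m) {
  if (m$tp + m$fp == 0) abort("precision undefined: no detections")
  100 * m$tp / (m$tp + m$fp)
}

#' @rdname precision
#' @export
recall <- function(m) {
  if (m$tp + m$fn == 0) abort("recall undefined: no true meals")
  100 * m$tp / (m$tp + m$fn)
}

#' @rdname precision
#' @export
fscore <- function(m) {
  p <- precision(m) / 100
  r <- recall(m) / 100
  if (p + r == 0) abort("F-score undefined: precision and recall both zero")
  2 * p * r / (p + r)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FP %d, FN %d, median delay %s min>\n",
              x$tp, x$fp, x$fn,
              if (length(x$delays)) format(stats::median(x$delays)) else "-"))
  invisible(x)
}

#' Blood-glucose risk indices
#'
#' The symmetrising transform `f(BG) = 1.509 ((ln BG)^1.084 - 5.381)` maps
#' the clinical glucose range onto a scale symmetric about zero (root near
#' 112.5 mg/dL).  LBGI is the mean of `10 f(BG)^2` over samples with
#' `f < 0`, HBGI the mean over samples with `f > 0`, and the risk index is
#' their sum.
#'
#' @param bg Glucose series (mg/dL), strictly positive.
#' @return A one-row tibble: `lbgi`, `hbgi`, `ri`.
#' @export
risk_indices <- function(bg) {
  if (length(bg) == 0 || any(!is.finite(bg)) || any(bg <= 0)) {
    abort("`bg` must be a non-empty, positive glucose series")
  }
  f <- 1.509 * (log(bg)^1.084 - 5.381)
  r <- 10 * f^2
  lbgi <- mean(r * (f < 0))
  hbgi <- mean(r * (f > 0))
  tibble(lbgi = lbgi, hbgi = hbgi, ri = lbgi + hbgi)
}

#' Glycaemic summary of a glucose series
#'
#' Mean glucose, percentage time in range (70 < BG < 180 mg/dL), above range
#' (BG >= 180) and below range (BG <= 70), plus the [risk_indices()].
#'
#' @param bg Glucose series (mg/dL), strictly positive.
#' @return A one-row tibble: `mean_bg`, `tir`, `tar`, `tbr`, `lbgi`,
#'   `hbgi`, `ri`.
#' @export
glycaemic_summary <- function(bg) {
  if (length(bg) == 0 || any(!is.finite(bg)) || any(bg <= 0)) {
    abort("`bg` must be a non-empty, positive glucose series")
  }
  ri <- risk_indices(bg)
  tibble(mean_bg = mean(bg),
         tir = 100 * mean(bg > 70 & bg < 180),
         tar = 100 * mean(bg >= 180),
         tbr = 100 * mean(bg <= 70)) |>
    dplyr::bind_cols(ri)
}

cvga_zone_levels <- c("A", "UpperB", "LowerB", "B", "UpperC", "LowerC",
                      "UpperD", "LowerD", "E")

# 3x3 grid over (min BG column, max BG row); columns: min >= 90, 70-90, < 70
# (hypo worsens rightwards), rows: max <= 180, 180-300, > 300
cvga_grid <- matrix(c("A",      "LowerB", "LowerC",
                      "UpperB", "B",      "LowerD",
                      "UpperC", "UpperD", "E"),
                    nrow = 3, byrow = TRUE)

#' Control-variability grid analysis point
#'
#' One CVGA point per subject over the assessment period: the minimum BG
#' (clamped to 50-110 mg/dL) against the maximum BG (clamped to
#' 110-400 mg/dL), classified into the standard nine zones.  Zone A is
#' accurate control (min >= 90, max <= 180); the B zones are benign
#' deviations; C, D and E grade increasingly serious failures, with
#' Upper/Lower naming the axis responsible (hyper- resp. hypoglycaemia).
#'
#' @param bg Glucose series (mg/dL) of one subject over the assessment
#'   period.
#' @return A one-row tibble: `min_bg`, `max_bg` (clamped) and `zone`.
#' @export
cvga_point <- function(bg) {
  if (length(bg) == 0 || any(!is.finite(bg))) {
    abort("`bg` must be a non-empty glucose series")
  }
  mn <- min(110, max(50, min(bg)))
  mx <- min(400, max(110, max(bg)))
  tibble(min_bg = mn, max_bg = mx, zone = cvga_zone(mn, mx))
}

#' @rdname cvga_point
#' @param min_bg,max_bg Minimum and maximum BG of the period (mg/dL).
#' @export
cvga_zone <- function(min_bg, max_bg) {
  col <- ifelse(min_bg >= 90, 1L, ifelse(min_bg >= 70, 2L, 3L))
  row <- ifelse(max_bg <= 180, 1L, ifelse(max_bg <= 300, 2L, 3L))
  factor(cvga_grid[cbind(row, col)], levels = cvga_zone_levels)
}

#' Paired comparison of per-subject metrics
#'
#' Shapiro-Wilk on the paired differences (at 0.05) gates the test choice: a
#' paired t-test when normality is accepted, a Wilcoxon signed-rank test
#' otherwise.  The significance threshold is Bonferroni-adjusted to
#' `0.05 / n_comparisons`.
#'
#' @param metric_a,metric_b Equal-length per-subject metric values under the
#'   two conditions (n >= 3).
#' @param n_comparisons Number of pairwise comparisons in the family.
#' @return A one-row tibble: `test`, `p_value`, `shapiro_p`, `alpha`,
#'   `significant`.
#' @export
paired_compare <- function(metric_a, metric_b, n_comparisons = 1L) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 3) {
    abort("need equal-length paired samples with n >= 3")
  }
  d <- metric_b - metric_a
  if (all(d == 0)) abort("all paired differences are zero; nothing to test")
  if (stats::sd(d) == 0) {
    abort("paired differences are constant; the normality gate is degenerate")
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value > 0.05) {
    ht <- stats::t.test(metric_b, metric_a, paired = TRUE)
    test <- "paired t-test"
  } else {
    ht <- stats::wilcox.test(metric_b, metric_a, paired = TRUE,
                             exact = FALSE)
    test <- "Wilcoxon signed-rank"
  }
  alpha <- 0.05 / n_comparisons
  tibble(test = test, p_value = ht$p.value, shapiro_p = sw$p.value,
         alpha = alpha, significant = ht$p.value < alpha)
}
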