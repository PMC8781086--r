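---
title: "Methods: quantile forecasting, meal detection and carbohydrate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile forecasting, meal detection and carbohydrate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mealsense implements a fully automated meal-handling layer for
closed-loop insulin delivery ("artificial pancreas") systems.  Hybrid
closed-loop systems require the user to announce meals and count
carbohydrates; missed, late and misestimated announcements are common and
degrade postprandial control.  The package detects unannounced meals from
the CGM signal and estimates their carbohydrate content, so a bolus can be
delivered without user input.  This vignette is the package's own account
of the model, the algorithms, the surrogate simulator the tests run
against, and the design decisions taken where more than one reasonable
choice existed.

## The multitask quantile forecaster

The core model is a sequence-to-sequence LSTM that predicts the last
20 minutes of the glucose trajectory — four 5-min steps — at three
quantiles.  The encoder consumes, per 5-min step, the CGM glucose
(mg/dL), the insulin delivered in the step (U) and the meal-record
carbohydrates (g) over a configurable history (default 24 steps = 2 h).
The decoder, initialised with the final encoder state, consumes only the
exogenous inputs (insulin, carbohydrates) of the forecast horizon — the
decoder never sees lagged glucose, so teacher forcing does not arise.
Three per-step linear heads emit the 2.5%, 50% and 97.5% quantiles,
giving a 95% prediction interval that captures the aleatoric noise in the
data (sensor error, behavioural variability) without assuming Gaussian
errors.

Training minimises the pinball (tilted) loss per head,

$$L_\tau(y, \hat y) = \begin{cases}\tau (y - \hat y) & y > \hat y\\
(1-\tau)(\hat y - y) & \text{otherwise,}\end{cases}$$

uniformly combined as $L = (L_{LB} + L_{M} + L_{UB})/3$.  At $\tau = 0.5$
the pinball loss is half the absolute error, so the median head is an MAE
regressor.  (Both branches are written in the standard non-negative form;
a loss must be bounded below for minimisation, and the median–MAE
equivalence only holds in this form.)

Training is two-stage: a population model on aggregated data from all
individuals (Adam, learning rate $10^{-3}$), then per-individual
fine-tuning at $10^{-4}$.  Both stages use batch size 128, at most 100
epochs, early stopping with patience 20 and minimum improvement
$10^{-4}$, and gradient-norm clipping at 1.0 (the clip is a stability
choice of this implementation).  Each individual's windows are split
80/20 chronologically — never shuffled — so validation is strictly
out-of-time.  Features are min–max normalised to [0, 1] with statistics
computed on the population training split and frozen into the model
bundle; fine-tuning and inference reuse them unchanged.  The LSTM and its
training loop are implemented in the package's own C++ (RcppArmadillo)
code with a single seeded RNG, so runs are bit-reproducible on one
thread.

**The meal input channel.**  The meal channel is the meal *record*
(grams deposited at the step of intake), not the announcement stream.  In
simulator-generated training data the record is exact while the
announcement behaviour (skips, delays, counting errors) corrupts only the
insulin channel.  This matters: if the carbohydrate input were the
announcements, every carbohydrate spike would co-occur with a bolus of
exactly proportional size, the two channels would be perfectly collinear,
and the network could attribute the postprandial rise to either — in
practice it then learns a near-zero or even negative carbohydrate
response, which breaks the inverse search below.  The behavioural
corruption of the insulin channel is precisely what identifies the
carbohydrate response.  During deployment the same channel carries the
accepted meal estimates (fully closed loop) or the announcements (hybrid
mode).  Meals enter as grams-at-step rather than as a pre-filtered
absorption signal; the network learns the absorption kinetics itself.

## Meal detection

At each step the forecast window is aligned so its final decoder step is
the present sample, and the present CGM value is compared with the upper
bound at that step.  A counter $k$ counts consecutive samples above the
upper bound and resets whenever the CGM falls back inside.  A flag is
raised when $k > 2$ — i.e. on the third consecutive exceeding sample,
15 minutes of persistent deviation — and the glucose rate of change is at
least 1 mg/dL/min.  The rate of change is the least-squares slope over
the last 3 CGM samples (10 min); the differencing scheme is not dictated
by the detection rule itself, and least squares damps single-sample
sensor noise.  Raising a flag resets $k$.  After an *accepted* estimate a
60-min refractory window suppresses further flags — matching the 1-h
basal suspension — after which re-estimation is permitted if the
exceedance persists, each supplementary estimate independently capped at
90 g.

## Carbohydrate estimation

With a flag active, the estimator searches for the meal size that
reconciles the forecast with the observation.  A candidate meal of $m_E$
grams is injected into the forecaster's carbohydrate channel at the
inferred onset (the first-exceedance sample minus the persistence, i.e.
20 min before the flag for a fresh run), the window is re-forecast, and
the error $|\hat y_M(t) - y_{CGM}(t)|$ at the present sample is compared
with a threshold $\epsilon$, the individual's validation MAE of the
median head (in mg/dL).  The error criterion uses only the final decoder
step — the step aligned with the present CGM value.  The search ascends
in 10-g increments until the error drops below $\epsilon$ or the 90-g cap
is reached, then backs off one coarse increment and re-runs in 1-g
increments, returning the first size meeting the threshold.  If a coarse
increment fails to *reduce* the error the candidate meal cannot explain
the excursion — the deviation violates carbohydrate dynamics — and the
estimate is discarded (0 g, no bolus); this check runs after every coarse
increment, terminating the search early.  Estimates that reach the cap
are returned as 90 g and flagged `capped`; on the surrogate scenario most
accepted estimates are capped, an overestimation bias that the weighted
bolus below is designed to absorb.  $\epsilon$ is static per individual;
recomputing it online as conditions drift is deliberately out of scope.

## Closed-loop harness

The detection layer is controller-agnostic; the packaged harness wires it
to a deliberately generic basal–bolus controller so its behaviour is easy
to reason about: a proportional–derivative basal modulation around a
120 mg/dL target, clamped to 0–3x the nominal basal, with basal suspended
below 80 mg/dL.  Automatic meal boluses are `0.5 * grams / carb_ratio` —
half-weighted because the feedback layer has already started responding
to the rise and the estimate may be capped high — with no correction
component ever combined with a meal bolus, and basal suspended for
exactly 1 h (12 steps) afterwards.  Three modes are wired: `NMA`
(feedback only), `MD` (feedback + detection/estimation boluses) and `MA`
(hybrid: announcement-driven, unweighted boluses at announcement time,
subject to the behaviour model's skips, delays and counting errors).

## The surrogate simulator

No public dataset pairs CGM, insulin and ground-truth meal times at this
granularity, so the package ships a surrogate type 1 diabetes simulator
and the tests quantify the method against it.  The physiology is a
minimal-model glucose compartment with insulin-proportional-to-glucose
utilisation (so glucose cannot cross zero), a two-compartment gut chain
(time-to-peak 40 min) and a two-compartment subcutaneous insulin chain
(time-to-peak 55 min), integrated with fixed-step RK4 at 1 min and
sampled at 5 min.  Defaults: basal 1 U/h holding a 120 mg/dL fasting
setpoint, insulin sensitivity 50 (mg/dL)/U at the setpoint, carbohydrate
gain 4 (mg/dL)/g, carb ratio 12 g/U, glucose effectiveness 0.005/min.

The scenario statistics are fixed, not tuning knobs: four daily meals of
mean size 70/100/30/80 g at 07:00/13:00/17:00/20:00, onset SD 60 min
(days resampled if jitter would reorder meals), size CV 10%; on average
2.5 announcements skipped and 2 delayed per week (delay uniform on
15–60 min — only the rate is externally constrained, the delay law is
this package's choice); counting error uniform on [−30%, +10%]; insulin
sensitivity modulated sinusoidally (amplitude 30% of base, period 24 h,
per-subject phase) and insulin absorption scaled by a per-day uniform
±30% multiplier.  CGM noise is AR(1) with stationary SD 7 mg/dL and
coefficient 0.7 — the standard shape of CGM error models; the magnitude
is a declared surrogate default, not an inferred one.

What the surrogate does *not* emulate: meal-composition (fat/protein)
effects on absorption, exercise, illness, sensor dropout and drift, pump
quantisation, and the full validated virtual-cohort physiology of
regulatory-grade simulators.  Passing tests therefore show that the
algorithmic chain is correct and well-calibrated under realistic
statistical structure — not that the same F-scores would be attained on a
regulatory-grade cohort; on this cleaner physiology detection is somewhat
easier, and measured F-scores run above what a harder simulator yields.

## Evaluation layer

Detections are matched to meals greedily in time order, each detection
claiming the most recent unmatched meal within 120 min before it;
matched = true positive, unmatched detection = false positive, unmatched
meal = false negative.  Greedy chronological matching is the documented
tie-break; it can occasionally fall one short of the optimal bipartite
matching, which the tests verify as an upper bound.  Precision, recall
(percent) and F (harmonic mean, fraction) follow; delays are summarised
by median, with mean ± SD also reported.  Glycaemic metrics: mean BG,
TIR (70 < BG < 180), TAR (≥ 180), TBR (≤ 70) — the boundary conventions
follow the printed inequalities — and the Kovatchev risk indices with the
standard symmetrisation constants (1.509, 1.084, 5.381, weight 10), whose
root sits near 112.5 mg/dL.  CVGA classifies each subject's
(min BG, max BG) over the whole assessment period into the standard
nine-zone grid (A best; Upper zones = hyperglycaemic deviations, Lower =
hypoglycaemic).  Paired per-subject comparisons use Shapiro–Wilk at 0.05
to choose between a paired t-test and a Wilcoxon signed-rank test, with
Bonferroni-adjusted thresholds.

## Numerical choices and degenerate inputs

* Quantile heads are unconstrained; crossing (upper < lower) is not
  prevented, only measured — it is rare on trained models and the tests
  bound its rate.
* A zero estimation threshold (validation MAE of 0) is degenerate and
  rejected rather than silently accepted.
* Zero-variance features normalise with unit scale instead of dividing
  by zero.
* Simulated glucose is checked for positivity and finiteness at every
  step; divergence aborts with the offending step.
* All randomness flows through named, derived seed streams (scenario,
  absorption, sensor noise, weight init, batch shuffling), so equal seeds
  give bit-identical runs and NMA/MD comparisons share identical noise.

## Problem sizes used by the shipped benchmark

The desk-scale benchmark behind the acceptance checks uses 3 surrogate
subjects, 3 simulated weeks of hybrid-mode training data each (population
stage capped at 25 epochs, fine-tuning at 8 — early stopping usually
binds first) and 3 held-out weeks of fully closed-loop MD evaluation per
subject, with the NMA arm run on identical seeds.  These sizes are the
package's chosen trade-off between statistical stability (about 190
pooled meals) and a training run that completes comfortably on a single
CPU; the scenario statistics above are never scaled.
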