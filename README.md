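# mealsense

Automatic detection of unannounced meals and estimation of their
carbohydrate content for closed-loop insulin delivery (artificial
pancreas) systems.

Hybrid closed-loop systems keep postprandial glucose in check only if the
user announces meals and counts carbohydrates before eating — and people
routinely skip, delay or misestimate those announcements. mealsense
implements a fully automated alternative, aimed at researchers working on
insulin-delivery algorithms:

* **Forecasting.** A multitask sequence-to-sequence LSTM (64 cells,
  implemented in the package's own RcppArmadillo code) predicts the last
  20 min of the glucose trajectory at the 2.5%, 50% and 97.5% quantiles,
  trained with the pinball loss
  L_τ(y, ŷ) = τ(y − ŷ) if y > ŷ, else (1 − τ)(ŷ − y),
  uniformly combined over the three heads. The (2.5%, 97.5%) pair forms a
  95% prediction interval capturing the aleatoric noise of the data.
  Training is two-stage: a population model on pooled data (Adam, lr 1e-3),
  then per-individual fine-tuning (lr 1e-4), batch 128, early stopping on a
  chronological 80/20 validation split.
* **Detection.** A meal flag is raised when the CGM exceeds the interval's
  upper bound for more than N = 2 consecutive samples (i.e. on the third,
  15 min of persistence) while glucose rises at ≥ 1 mg/dL/min.
* **Estimation.** An inverse search injects candidate meal sizes into the
  forecaster's carbohydrate input — 10-g coarse steps, then 1-g refinement —
  until the median forecast matches the observed CGM to within ε, the
  individual's validation MAE; estimates are capped at 90 g and discarded
  if adding carbohydrates fails to reduce the error.
* **Closed loop.** A generic basal–bolus harness wires everything to a
  surrogate type 1 diabetes simulator in three modes: NMA (feedback only),
  MD (feedback + detection/estimation, bolus = 0.5 × grams/ICR with a 1-h
  basal suspension) and MA (announcement-driven hybrid control).
* **Evaluation.** Precision/recall/F-score with a 120-min true-positive
  window, detection delays, TIR/TAR/TBR, LBGI/HBGI/RI risk indices, CVGA
  zoning and paired Shapiro–Wilk-gated significance tests.

The methods vignette (`vignettes/meal-detection-methods.Rmd`) documents
the model, the surrogate simulator's physiology and scenario statistics,
and every open design decision.

## Worked example

Simulate a subject for a week of hybrid closed loop, train the forecaster,
and run a fully closed-loop (MD) week against held-out meals:

```r
library(mealsense)

subject <- subject_params()                      # 1 U/h basal, ICR 12 g/U
train_ev <- sample_scenario(days = 7, seed = 21) # 70/100/30/80 g meal protocol
ma <- controller_config(mode = "MA", carb_ratio = subject$carb_ratio)
train_tl <- run_closed_loop(subject, train_ev, days = 7, control = ma,
                            seed = 22)$timeline

cfg <- training_config(max_epochs = 12)
bundle <- train_population(train_tl, cfg) |>
  finetune_individual(train_tl)
glance(bundle)
#> # A tibble: 1 × 7
#>   stage      epochs best_epoch val_loss validation_mae lstm_cells n_params
#>   <chr>       <int>      <int>    <dbl>          <dbl>      <int>    <int>
#> 1 individual     12         12  0.00886           9.92         64    34755

test_ev <- sample_scenario(days = 7, seed = 31)
md <- run_closed_loop(subject, test_ev, days = 7,
                      control = controller_config(mode = "MD",
                                                  carb_ratio = subject$carb_ratio),
                      bundle = bundle, seed = 33)
glance(match_events(test_ev, dplyr::filter(tidy(md), accepted)))
#> # A tibble: 1 × 9
#>      tp    fp    fn precision recall fscore median_delay_min mean_delay_min sd_delay_min
#>   <int> <int> <int>     <dbl>  <dbl>  <dbl>            <dbl>          <dbl>        <dbl>
#> 1    27     0     1       100   96.4  0.982             24.6           28.3         12.4
```

The bundle's `validation_mae` (9.9 mg/dL here) is the ε threshold the
estimator uses. Of the 28 held-out meals (including the hard 30-g snacks),
27 are flagged within the 120-min window at a median delay of ~25 min, with
no false positives. `glycaemic_summary()`, `cvga_point()` and
`paired_compare()` then quantify the control benefit, and
`autoplot(md$timeline)` shows the glucose traces.

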