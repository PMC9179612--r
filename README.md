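# herdsense

Behavior classification for dairy cattle from neck-collar accelerometer
streams.

Collar-mounted triaxial accelerometers (25 Hz, ±2 G, 1 mG resolution) are
the workhorse sensor of precision livestock farming: from their signal one
can recover how much time a cow spends standing, lying, ruminating and
eating — the *time budget* that underpins health and welfare monitoring.
`herdsense` implements the complete classification pipeline for such
streams, aimed at researchers who work with raw, open collar data rather
than the lumped outputs of commercial systems:

* **windowing** — decorated streams $(X_t, Y_t, Z_t, B_t)$ are split into
  non-overlapping 10-minute windows of 15,000 samples;
* **window labeling** — each window gets a class pair $(C_1, C_2)$: the
  most frequent behavior, and the second behavior when it covers at least
  a fraction `fmin` (default 0.4) of the window; rare pairs are lumped
  into a 15-member reduced set with rarity threshold `flow` (default 0.01);
* **features** — 23 features per window from 5-second sub-window series
  (RMS and max of per-axis mean / absolute mean / standard deviation
  series; the dynamic body acceleration summaries VeBDA and OBDA; the
  three inter-axis correlations), screened by cross-correlation at
  |r| > 0.75;
* **classifiers** — five CART decision trees over nested class sets S1–S5
  (all behaviors; ruminating/not; standing/lying; eating/not; class
  pairs), combined by a weighted class-containment vote
  $W_k = \sum_i w_i \, [k \in s_i]$, $S_6 = \arg\max_k W_k$;
* **evaluation** — stratified 75/25 partitioning, per-classifier accuracy
  and confusion matrices, partition-sensitivity analysis, and time-budget
  accuracy $100\,(1 - \sum_b |T_{est,b} - T_{act,b}| \, / \, 2\sum_b T_{act,b})$
  with $T_{W,b} = \Delta t \sum_{B_t \in W} \delta_{B_t,b}$;
* **a synthetic herd generator** — a semi-Markov bout schedule plus
  per-behavior postural/spectral signatures produces decorated streams
  with known ground truth, so the whole pipeline is testable without farm
  recordings.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects support `tidy()`/`glance()`, and result types have
`autoplot()` methods.

## Worked example

Simulate five 6-hour collar recordings, train the classifier bank on a
stratified 75% learning split, and score the held-out windows:

```r
library(herdsense)

study <- run_study(hours = 6, seeds = 1:5)
study
#> <herdsense_study> 180 windows (46 test), 8 retained features
#>   accuracy: S1 93.5%, S2 93.5%, S3 93.5%, S4 93.5%, S5 89.1%, S6 93.5%
#>   time accuracy: 94.18%
```

180 ten-minute windows were pooled; 8 of the 23 features survived the
correlation screening; the five trees score 89–94% on the 46 test windows
and the combined vote S6 reaches 93.5%. Reconstructing the time budget of
the test windows from the S6 estimates:

```r
tidy(study$time_budget)
#> # A tibble: 8 × 4
#>   behavior actual_s estimated_s rel_error_pct
#>      <int>    <dbl>       <dbl>         <dbl>
#> 1        1     3863        3600         -6.81
#> 2        2     7080        7200          1.69
#> 3        3     1999        2400         20.1
#> 4        4     7632        7800          2.20
#> 5        5     5683        6600         16.1
#> 6        6      370           0       -100
#> 7        7      490           0       -100
#> 8        8      483           0       -100
```

The sustained behaviors (lying, ruminating-lying) are recovered within a
few percent; the brief behaviors (drinking, walking, other) occupy so few
whole windows that the window-quantized estimate misses them — exactly the
quantization effect the time-accuracy metric summarizes (here 94.2%
overall). Lower-level entry points (`simulate_stream()`,
`split_windows()`, `window_labels()`, `window_features()`,
`reduce_features()`, `train_classifier_bank()`, `combine_estimates()`,
`time_budget()`) expose each stage; a thin command-line front end with
`simulate` / `features` / `train` / `predict` / `evaluate` /
`sensitivity` subcommands ships in `inst/cli/herdsense.R`.

See the vignette (`vignettes/behavior-classification.Rmd`) for the model,
its parameters, the simulator's assumptions, and known limitations.

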