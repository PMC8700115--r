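# harsense

Sensor selection and sequence classification for wearable human activity
recognition (HAR).

Wearable HAR systems classify a person's activity from body-worn inertial
sensors, but deployments disagree on *how many* sensors to wear and *where*.
`harsense` implements an information-theoretic answer plus a recurrent
attention classifier to exploit it:

* **Information-gain sensor model.** Every candidate sensor node
  `K_i` owns `C_i` data channels. Each channel `F` is discretised (default:
  20 equal-frequency bins fit on training data) and scored by the reduction
  in label entropy `IG(F, A) = H(A) − H(A | F)`, with
  `H(A) = −Σ_j P(A_j) log₂ P(A_j)`. A sensor's gain is the sum over its
  channels, `IG(K_i) = Σ_l IG(K_il)` (a per-channel mean mode `IG(K_i)/C_i`
  is also provided), and the top-`n` sensors by rank are selected greedily.
* **Preprocessing.** Linear interpolation of missing samples (nearest-value
  extension at the edges), sliding-window segmentation (default length 24,
  stride 12, window labelled by its last sample), seeded train/validation
  splits, channel selection.
* **Attention BiLSTM classifier.** Batch-normalised input, two stacked
  bidirectional LSTM layers emitting per-timestep states, temporal attention
  pooling (`a_t = softmax_t(u_tᵀ u_w)`, `v = Σ_t a_t H_t`), dense softmax
  output. Trained with Adadelta (initial rate 1.0, batch 16), early stopping
  on training loss (patience 50) and checkpointing of the best validation
  weighted F1. Forward and backward passes are implemented in vectorised R
  and verified against numerical gradients.
* **Evaluation.** Confusion matrices and class-support-weighted F1
  `F1 = Σ_j (N_j/N) · 2P_jR_j/(P_j+R_j)` — the right metric when a Null
  class dominates.
* **Synthetic data.** A seeded multi-sensor stream generator with planted
  per-sensor informativeness, so ranking, windowing, training and evaluation
  are testable end to end without downloads.
* **OPPORTUNITY loader.** Optional reader for the UCI OPPORTUNITY Activity
  Recognition challenge files (113-channel subset, ML and GR label tracks,
  the challenge train/test split). The dataset is an opt-in download from
  <https://archive.ics.uci.edu/ml/datasets/OPPORTUNITY+Activity+Recognition>;
  nothing is fetched automatically.

## Worked example

Rank sensors on a synthetic stream with a planted informativeness gradient,
keep the top two, train the classifier on their channels and score held-out
data:

```r
library(harsense)

spec   <- synthetic_spec(T = 12000L, seed = 11)   # 5 sensors, gradient 0.9..0.05
rec    <- interpolate_missing(generate_recording(spec))
layout <- synthetic_layout(spec)

report <- rank_sensors(rec, layout, task = "activity")
report
#> <infogain_report>
#>  sensor Ci gain_sum gain_mean rank_sum rank_mean
#>      s1  3  0.87753  0.292509        1         1
#>      s2  3  0.58775  0.195915        2         2
#>      s3  3  0.33612  0.112040        3         3
#>      s4  3  0.06719  0.022398        4         4
#>      s5  3  0.01639  0.005465        5         5
```

The summed gains recover the planted order `s1 > s2 > s3 > s4 > s5`
(informativeness 0.9, 0.7, 0.5, 0.2, 0.05): gain in bits tracks how strongly
a sensor's channels separate the five activity classes. Select the top two
sensors and train on their six channels:

```r
ch    <- select_top_sensors(report, n = 2, mode = "sum")   # channels 1..6
train <- segment_windows(rec, "activity", 24, 12)
test  <- segment_windows(interpolate_missing(generate_recording(
           synthetic_spec(T = 4000L, seed = 99))), "activity", 24, 12)

mc  <- model_config(c(24, length(ch)), n_classes = 5,
                    recurrent_units = 16, seed = 42)
fit <- train_model(build_model(mc), select_channels(train, ch),
                   train_config(max_epochs = 8, seed = 7))
pred <- predict(fit$model, select_channels(test, ch))
eval_report(test$labels, pred$labels, 5, class_names = test$class_names)
#> <eval_report> N = 332, weighted F1 = 0.9117
#>  class support precision recall     f1 weight class_name
#>      0     160    0.9059 0.9625 0.9333 0.4819       Null
#>      1      17    1.0000 0.7647 0.8667 0.0512       act1
#>      2      49    0.9091 0.8163 0.8602 0.1476       act2
#>      3      43    0.9512 0.9070 0.9286 0.1295       act3
#>      4      63    0.8906 0.9048 0.8976 0.1898       act4
```

Two of five sensors reach a weighted F1 of 0.91 on this stream — the point
of gain-ranked selection is that the first few sensors carry most of the
usable signal. `run_sensor_sweep()` automates the full top-`n` curve,
`run_ablation()` compares layer stacks, and `run_stability()` checks
robustness to halving the training data.

A thin command-line front end over the same functions ships in
`inst/cli/har.R` (`simulate`, `rank-sensors`, `segment`, `train`,
`evaluate`, `sweep`, `ablate`, `stability`).

## Scope notes

Full-scale benchmark training (192 units per direction on the complete
OPPORTUNITY training set) uses the same code path but is an hours-long,
GPU-class computation; the shipped experiment defaults are desk-scale. See
the methods vignette (`vignettes/harsense-methods.Rmd`) for the model,
parameter and design rationale.
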