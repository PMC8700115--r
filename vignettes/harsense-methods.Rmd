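---
title: "Sensor selection and sequence classification for wearable activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor selection and sequence classification for wearable activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harsense)
```

## The problem

Wearable human activity recognition (HAR) classifies what a person is doing
from body-worn inertial sensors (accelerometers, gyroscopes, magnetometers).
Two practical questions dominate system design:

1. **Where should sensors go, and how many are needed?** Deployments differ
   wildly in sensor count and placement, and each extra node costs money,
   power and wearer comfort.
2. **How should the multichannel time series be classified?** Activities
   unfold over time, different moments of a movement carry different amounts
   of evidence, and class distributions are heavily imbalanced (most samples
   belong to a "Null" class of no interest).

`harsense` addresses both: an information-gain model that ranks candidate
sensor positions by how much their raw signals reduce uncertainty about the
activity label, and a bidirectional LSTM classifier with temporal attention
pooling trained on sliding windows of the selected channels.

## The information-gain sensor model

Each deployable sensor node $K_i$ owns $C_i$ data channels (one per axis per
modality). For a discrete feature $F$ and activity label $A$ with classes
$A_1 \dots A_m$,

$$\mathrm{IG}(F, A) = H(A) - H(A \mid F), \qquad
  H(A) = -\sum_{j=1}^m P(A_j)\log_2 P(A_j),$$

with the conditional entropy $H(A\mid F)=\sum_v P(F{=}v)\,H(A \mid F{=}v)$
computed from the empirical joint counts. The gain of a sensor is the sum
over its channels,

$$\mathrm{IG}(K_i) = \sum_{l=1}^{C_i} \mathrm{IG}(K_{il}),$$

and sensors are selected greedily: rank by gain, keep the top $n$. A second
ranking mode divides by $C_i$ so that nodes with many channels (e.g. a
16-channel shoe sensor vs. a 3-channel accelerometer) are not favoured merely
by size. Greedy selection here means rank-prefix selection: gains are not
re-evaluated after each pick, since per-channel gains are computed
marginally and summing them is already the selection criterion. Ties in
either ranking break by sensor declaration order, so results are
deterministic.

Information gain is computed on the **raw, unwindowed** training samples:
the windowed training tensor repeats samples (stride < window length), which
would distort the joint counts.

### Discretisation

Information gain requires discrete feature values; inertial channels are
continuous. Channels are binned before counting. The default is
**equal-frequency binning with 20 bins**, fit on the training samples of the
channel itself: quantile edges adapt to the heavy-tailed, multi-modal
amplitude distributions of accelerometer data, whereas equal-width bins can
put almost all mass in one bin. Equal-width binning is available
(`strategy = "equal_width"`), bin count is a parameter, and values outside
the fitted range clamp to the end bins. A constant channel collapses to a
single bin and contributes zero gain, which is the correct degenerate
answer. The logarithm base defaults to 2 (gains in bits) and is exposed
because published gain tables often leave the base unstated; rankings are
invariant to the base, absolute magnitudes are not. For the same reason,
absolute gain values from other implementations are reproducible only when
their discretisation is known; orderings are the robust comparison.

## Preprocessing

* **Missing samples.** Any non-finite value in an input file is a missing
  marker. Missing values are filled by linear interpolation along time
  within each channel. Leading/trailing runs, where interpolation has only
  one anchor, take the nearest observed value: this preserves the channel's
  scale and fabricates no trend. A channel with no observed values at all is
  an error rather than a guess.
* **Segmentation.** A sliding window of length $S = 24$ samples with stride
  12 (at 30 Hz: 0.8 s windows, 50% overlap) cuts each continuous recording
  into $\lfloor (T-S)/\mathrm{step} \rfloor + 1$ windows. Each window is
  labelled by its **last** sample's label — the natural choice for online
  recognition, where the window ends "now". Windows spanning an activity
  boundary are kept (the last-sample rule decides their label); discarding
  them would misrepresent deployment conditions. Windows never span
  recording boundaries: separate files are separate sessions, and a window
  across them would contain a physically impossible transition.
* **Validation split.** A uniformly random, seed-reproducible 5% of the
  training windows is held out to monitor loss and weighted F1 after each
  epoch.

## The classifier

The default stack is **BN + 2×BiLSTM + Attention + Dense**:

* **Batch normalisation** of the input, per channel over batch × time
  (training uses batch statistics and maintains running estimates; inference
  uses the running estimates, which also makes prediction batch-size
  invariant). Normalising per (channel, timestep) instead is not offered:
  inertial channels are stationary enough within a 24-sample window that
  per-channel statistics are the conventional choice.
* **Two bidirectional LSTM layers**, 192 units per direction by default,
  with tanh candidate activations and sigmoid gates; forget-gate biases
  start at 1. Both layers emit hidden states at every timestep. Forward and
  reverse states are **concatenated** by default (giving a 384-dimensional
  state); an additive mode (`bidir_combine = "sum"`, a tanh of a learned
  scalar-weighted sum) is provided because the combination operator is a
  genuine design freedom.
* **Temporal attention pooling.** Each timestep's state $H_t$ is projected
  ($u_t = \tanh(W_w H_t + b)$), scored against a trainable context query
  $u_w$ by dot product, and the scores are softmax-normalised over time:

  $$a_t = \mathrm{softmax}_t(u_t^\top u_w), \qquad v = \sum_t a_t H_t.$$

  The weights lie on the probability simplex, so the pooled context vector
  is a convex combination of the per-timestep states — moments that carry
  more evidence about the activity receive more weight.
* **Dense softmax output**, one unit per class; the predicted class is the
  argmax, with exact ties resolved to the lowest class index for
  determinism.

All parameters use a symmetric uniform fan-based initialisation. Forward and
backward passes (backpropagation through time included) are implemented in
vectorised R and verified against central-difference numerical gradients in
the test suite.

### Alternative stacks

Ablation catalogues express architectures as token lists
(`ablation_structures()`). Two placement rules make every catalogued stack
well-defined:

* An `attention` token followed only by `bn`/`dense` **pools** the sequence
  into the context vector. An `attention` token followed by further
  recurrent or attention layers cannot pool (a recurrent layer needs a
  sequence), so it instead **re-weights** the sequence — timestep $t$ is
  scaled by its attention weight $a_t$ — and keeps the time axis.
* A stack with no pooling attention classifies from the **last timestep's**
  state, the minimal-deviation reading of "remove the attention layer".

### Training protocol

Adadelta (decay 0.95, $\varepsilon = 10^{-6}$) with learning-rate multiplier
1.0 and batch size 16; mean cross-entropy loss. Training stops when the
epoch training loss has not decreased for 50 consecutive epochs (patience),
with a hard cap of `max_epochs` (default 300) so runs are bounded. After
each epoch the held-out windows are scored, and the parameter snapshot with
the **highest validation weighted F1** is what `train_model()` returns. All
stochastic elements — initialisation, the validation split, each epoch's
shuffle — consume seeds derived from the configs' seeds, so two runs with
the same seeds produce identical histories.

## Evaluation

With a dominant Null class, accuracy is misleading; the headline metric is
the class-support-weighted F1

$$F_1 = \sum_j \frac{N_j}{N} \cdot \frac{2 P_j R_j}{P_j + R_j},$$

where $N_j$, $P_j$, $R_j$ are class $j$'s support, precision and recall. A
class with $P_j + R_j = 0$ contributes 0 at weight $N_j/N$ (the standard
convention that keeps the sum finite); classes absent from the truth have
zero weight. Confusion matrices are reported with actual classes on rows,
predicted on columns, and can be rendered as a shaded heat table
(`plot_confusion()`).

## The synthetic generator

Real benchmark recordings (e.g. the UCI OPPORTUNITY challenge data) are an
opt-in download, so the package ships a seeded generator
(`synthetic_spec()` / `generate_recording()`) that emulates the regime the
pipeline targets:

* piecewise-constant labels with geometric dwell times (default mean 90
  samples = 3 s at 30 Hz, the simplest persistent-activity process);
* imbalanced class priors with a dominant Null class (default 40% Null,
  four activities at 15%);
* several sensors, each owning a contiguous channel block (default five
  3-channel sensors);
* per-sensor **informativeness** in $[0,1]$ scaling a class-conditional mean
  signal (default gradient 0.9, 0.7, 0.5, 0.2, 0.05), plus unit Gaussian
  noise and 2% missing samples.

The class-mean table is drawn **once** from a dedicated internal seed — per
class and within-sensor axis, shared across sensors, and standardised per
axis to zero mean and unit spread across classes — so informativeness is
the only systematic difference between sensors and `planted_ranking()` is
unambiguous ground truth for the information-gain ranking to recover. Two
weaker designs fail quietly: redrawing the means per recording lets their
random spread dominate adjacent informativeness levels (the "planted order"
is then not actually planted), and skipping the standardisation ties the
class separation — and hence whether a "separable" stream is separable at
all — to the luck of a single draw. With the standardised table the
per-channel signal-to-noise ratio is exactly
`informativeness_s / noise_sd`.

What the generator does **not** emulate: biomechanically realistic motion
(spectral structure, gravity components, inter-channel phase), sensor drift,
label noise, or inter-subject variability. Passing tests on synthetic data
therefore demonstrate that the machinery is correct — ranking recovers a
planted gradient, the classifier learns a separable stream, seeds reproduce
— not that any particular F1 level will be reached on real recordings.

## Working with OPPORTUNITY challenge files

`load_opportunity()` reads the dataset's native whitespace-delimited `.dat`
sessions (250 columns; the URL is in the README and the data are never
downloaded automatically). The default column specification keeps the
challenge's standard 113-channel subset and reads the Modes-of-Locomotion
(ML, 5 classes) and mid-level gesture (GR, 18 classes) label columns, with
Null mapped to class id 0 in both tasks; the gesture label column is a
documented option since the files carry several gesture tracks.
`challenge_split()` applies the challenge protocol: ADL4 and ADL5 of
subjects 2 and 3 are the test set, all other Drill/ADL sessions of subjects
1–3 train, and subject 4 (noise-injected for a different challenge track) is
excluded. `opportunity_layout()` ships the 19-node sensor layout over the
113 channels (twelve 3-channel accelerometers, five 9-channel IMUs, two
16-channel shoe sensors).

## Experiment drivers and problem sizes

* `run_sensor_sweep()` — rank sensors on raw training data, then for each
  `n` restrict to the top-`n` sensors' channels, retrain from scratch with
  the same seeds and score test weighted F1. Channel sets are nested by
  construction.
* `run_ablation()` — one model per layer stack, shared seeds and splits.
* `run_stability()` — train on two disjoint random halves of the training
  windows, score both on the common test set.

Every driver retrains fresh models with identical seeds so that only the
factor under study varies. The package's default experiment profile is
desk-scale — tens of recurrent units, tens of epochs, synthetic streams of
$10^4$–$2\times10^4$ samples — chosen so a full pipeline run takes minutes
on one CPU core. The full-size profile (192 units per direction, patience
50, the complete OPPORTUNITY training set) is exactly the same code with
larger numbers and is practical on a GPU-class budget; nothing in the
implementation assumes the small profile.

## Numerical choices and edge cases

* Entropy uses the $0\log 0 = 0$ convention; information gain is clipped at
  0 to absorb floating-point round-off (it is non-negative in exact
  arithmetic).
* Softmaxes subtract the row maximum before exponentiating; cross-entropy
  clamps probabilities at $10^{-12}$.
* `train_val_split()` sizes the validation half by `round(fraction * n)`;
  an `n < 2` dataset cannot be split and errors.
* Prediction on an empty dataset returns empty outputs rather than erroring
  (useful in sweeps over rare classes).
* Early stopping counts *strict* loss decreases; a flat loss from epoch 1
  stops training at epoch `patience + 1`.

## Known limitations

* Training is CPU-bound, single-threaded R; the full 192-unit,
  113-channel configuration is hours of compute, which is why experiment
  defaults are desk-scale.
* Information gain treats channels marginally; redundancy between sensors is
  not modelled (a deliberately simple criterion — joint selection methods
  such as mRMR are out of scope).
* The generator's geometric dwell times make activity segments memoryless;
  real activity durations are not.
* Checkpoints are R serialisations (`.rds`); they are not portable to other
  frameworks.
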