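---
title: "Recognizing athletic movements from wearable inertial arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing athletic movements from wearable inertial arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A player wears five inertial measurement units — pelvis, both thighs, both
shanks — each with a tri-axial accelerometer (±16 g) and gyroscope
(±2000 °/s) sampled at 500 Hz. From these 30 signal channels the package
recognizes five short athletic movements: *jog*, *sprint* (sustained,
periodic) and *pass*, *shoot*, *jump* (one-shot, explosive). The pipeline
has four stages:

1. **Activity isolation** trims low-activity stretches so training windows
   contain the target movement.
2. **Dataset construction** cuts 1-second windows (75% overlap), balances
   classes by undersampling, and optionally max-abs-scales each channel.
3. **Classification** trains convolutional networks — seven weight-sharing
   variants, optionally followed by an LSTM or bidirectional LSTM — with
   ADAM under staged learning-rate schedules.
4. **Whole-recording evaluation** slides a 1-second window over a
   recording, routes each window through a binary low/high-activity gate
   and the classifier, reduces window predictions to a per-timestep
   timeline by best-score selection, and removes implausibly short runs.

# The synthetic corpus

The kind of proprietary athlete recordings this method targets cannot be
redistributed, so `synthesizeCorpus()` generates scripted sessions with the
statistical structure the pipeline relies on. Design of the signal model:

* **Low activity** is a gravity offset of 1 g on one accelerometer axis per
  location plus Gaussian noise (default sd 0.05 g; gyroscopes get
  noise at a 40×-larger scale in °/s). This gives the "low magnitude, low
  variance" background the gate and the isolation threshold assume.
* **Oscillation in quadrature.** Activities superimpose a limb oscillation
  written as $a\,\sin\phi(t)$ and $a\,\cos\phi(t)$ on the two horizontal
  axes plus a weaker second harmonic on the vertical axis. The quadrature
  layout makes the accelerometer *norm* smoothly elevated
  ($\sqrt{1+a^2}$-ish) for the entire labeled interval — as in real gait,
  where the limb never stops accelerating mid-cycle — rather than dipping
  through the baseline twice per cycle, which would fragment any
  norm-threshold detector in a way real recordings evidently do not.
* **Periodic classes** run the oscillation for the whole interval: jog at
  2.5 Hz with shank amplitude 1.2 g, sprint at 3.5 Hz with 2.5 g; thighs
  and pelvis get scaled-down amplitudes. **Explosive classes** are a single
  enveloped burst (cosine ramps of 0.1 s, flat plateau): pass 8 Hz/3.5 g
  and shoot 11 Hz/7 g on one thigh+shank, jump 5 Hz/5 g on both shanks and
  pelvis. Duration ranges: periodic 4–8 s, explosive 1.0–1.6 s; low gaps
  between activities are drawn from 3–5 s.
* **Phase jitter** (a slow random walk), ~0.7 Hz amplitude modulation, and
  per-subject amplitude (±15%) and frequency (±8%) multipliers — drawn once
  per subject — provide within- and between-subject variability.
* **Determinism.** Each recording's seed is a fixed function of the corpus
  seed and a recording counter, so a corpus regenerates bit-identically and
  recordings can be generated independently.

Amplitudes, frequencies and durations are plausible values for adult
football movements, chosen once when the generator was designed; they are
*not* estimates of any real dataset. What passing tests on this corpus
shows is that the algorithms are implemented correctly and that the
pipeline's assumptions are self-consistent — not that the reported
accuracies transfer to real athletes. The generator deliberately omits
orientation dynamics (gravity never rotates between axes), soft-tissue
artifacts, sensor drift and inter-class amplitude overlap, all of which
make real data harder.

# Activity isolation

For each location the per-timestep Euclidean norm of the accelerometer
triad is compared against a threshold $c\cdot\text{mean(norm)}$. A
detection is a maximal run of timesteps *strictly* above the threshold
lasting at least one block (50 timesteps = 0.1 s): the run's first
timestep is the onset found by scanning a 50-step window forward, its last
is the offset found by the mirrored backward scan. Ties at the threshold
count as low activity (conservative). Per-location detections are combined
by interval union, merging overlaps and adjacency. All maximal qualifying
runs are reported, not only the first, so recordings containing several
activities are handled.

The multiplier $c$ depends on the recording's movement kind: 1.0 for
periodic recordings, 1.5 for explosive ones. The kind is decided by the
interquartile range of the min–max-normalized *global* norm (the Euclidean
norm of the stacked 15-dimensional accelerometer vector): periodic iff
IQR > 0.12. The rationale: a sustained activity keeps the norm elevated
for a sizable fraction of the recording, pushing the 75th percentile into
the elevated band; a sub-second burst does not. Two readings in this stage
were genuinely open and are resolved as follows: the global norm is the
norm of the stacked vector (not a combination of per-sensor norms), and
the backward scan is read as the mirror image of the forward one. A
constant norm has zero range; min–max normalization maps it to all zeros
(IQR 0, explosive) with a logged note.

# Dataset construction

Windows are 500 timesteps (1 s). Training windows advance by
`window × (1 − overlap)`; an interval of length $L$ yields
$\lfloor (L-500)/\text{step}\rfloor + 1$ windows, zero (with a note) when
$L < 500$. Undersampling reduces every class to the minority count.
Splits are repeated random subsampling (default 5 folds of 70/30), each
fold drawn with a seed derived from the master seed. Two points where the
package makes its own choice:

* **Split granularity.** The default keeps all windows of one recording on
  the same side of the split, because 75%-overlapping windows from the
  same interval are near-duplicates and window-level splitting leaks them
  across partitions. Window granularity remains available
  (`granularity = "window"`) to mirror the classic window-level protocol.
* **Balancing** is applied within the train and test partitions
  independently, after splitting, so the test partition is balanced too
  and accuracy remains an unbiased summary.
* **Scaling reference.** Max-abs scaling divides each channel by the
  maximum absolute value of the reference channel; all-zero channels stay
  zero. The default reference is the whole source recording (a
  "calibration" reference), which preserves *relative* amplitude between
  windows — important because pass and shoot differ mainly in amplitude,
  which per-window self-scaling would erase. Per-window scaling is
  available as the config option `scale = "window"`.

`handcraftedFeatures()` computes the nine per-channel statistics used by
traditional baselines (mean, median, sd, max, min, skewness, kurtosis, sum
and max of the real Fourier coefficient parts). Skewness and kurtosis use
population moments and are defined as 0 for zero-variance channels, so the
extractor is total on degenerate inputs.

# The model zoo

All convolutions are *valid* (no padding) with ReLU; pooling acts on the
time axis only. A sensor *group* is one modality triad (3 axes): 10 groups
with gyroscopes, 5 without — this grouping is forced by the 3-row filters,
which can only span one triad. The seven trunk variants:

| variant | filter height | sharing |
|---|---|---|
| `c1d_share` | 1 | one bank for all 30/15 signal rows |
| `c1d_per_sensor` | 1 | an independent bank per triad |
| `c1d_combined` | 1 | both of the above, stacked |
| `c2d_share` | 3, spatial stride 3 | one bank for all triads |
| `c2d_per_sensor` | 3, aligned per triad | an independent bank per triad |
| `c2d_all` | full height | a single array-wide bank |
| `c2d_combined` | — | all three 2-d variants, stacked |

1-d trunks are Conv(16,(1,5))→MaxP(1,4)→Conv(32,(1,5))→MaxP(1,4); 2-d
trunks use 32 then 64 filters. In per-sensor variants both stages keep
per-group banks. Combined variants run their constituent trunks in
parallel and stack the feature maps *along the spatial axis* — for the 2-d
combination the three branches have heights 10, 10 and 1, so stacking is
the only concatenation that type-checks, and it matches the "one on top of
the other" picture. `c2d_per_sensor` applies each triad's bank at its own
rows, which is what a stride-3 convolution with group-specific filters
computes.

Heads: CNN-only models flatten into dropout→FC(128, ReLU)→dropout→FC(5,
softmax). CNN+RNN models first apply the full-height bridge convolution
Conv(128,(d,1),1), collapsing space so the time axis becomes a 30-step
feature sequence for an LSTM or bLSTM of 128 units, then the same FC
stack. Recurrent-only models feed the raw channels as the sequence
features (no input projection). Dropout defaults to 0.5 before each fully
connected layer; the rate is config-exposed since only its placement, not
its value, is standard. All widths scale with `widthScale`
(`desk = TRUE` sets 0.25 — filter counts 4/8/8/16, 32-unit bridge, LSTM
and FC). `outputShape()`/`weightCount()` compute the declared arithmetic;
`realizedShapes()`/`realizedWeightCount()` confirm it on the live model.

The engine itself is reverse-mode differentiation written against base
BLAS: im2col patch extraction for convolutions, pmax-chain max-pooling,
full BPTT through the (bi)LSTM, inverted dropout, softmax cross-entropy
and ADAM. Gradient correctness is pinned by finite-difference tests.

# Training protocol

ADAM with $\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-8}$; batch 32; at
most 200 epochs. Learning rates: CNN-only $10^{-3}$ decaying to 75% every
10 epochs; RNN-only $10^{-4}$, 50% decay; CNN+RNN $5\cdot10^{-5}$, 75%
decay. Scaled inputs multiply the initial rate by 10 (the signals are an
order of magnitude smaller). Early stopping halts after 5 consecutive
epochs in which the validation loss fails to decrease by more than
$10^{-6}$ — "improve" must be given a tolerance to be computable, and
$10^{-6}$ makes essentially any decrease count. Two deliberate,
documented simplifications: the test partition doubles as the
early-stopping validation set (no third split is described for this
protocol; this makes the stopping rule slightly optimistic), and
last-epoch weights are returned rather than best-epoch weights.

# Whole-recording evaluation

The binary gate thresholds a statistic of the window's accelerometer norm;
the standard deviation is the default metric because it attains the
largest two-sample Kolmogorov–Smirnov separation between low- and
high-activity windows in our gate-construction experiment (`gateSamples()`
+ `ksStatistic()`). `fitGate()` sweeps a 512-point threshold grid over the
observed metric range and keeps the F1-maximizing threshold, breaking ties
toward the larger (more conservative) threshold. The gate always sees raw
signals — it sits in front of the model, and its statistic would otherwise
depend on the scaling reference.

Sliding evaluation moves the 1-s window in steps of 10–100 ms (default
50 ms). Each window is gated; high windows get softmax probabilities, and
a maximum probability below 0.95 demotes the window to `other_high` so
movements outside the five classes are not forced into them. *Best-score
postprocessing* assigns every timestep the highest-confidence prediction
among the windows covering it; ties break toward the later-starting
window. Low-gated windows carry confidence 1 by convention so that gate
decisions dominate; timesteps covered by no window are `low` with
confidence 0. *Outlier removal* relabels maximal runs shorter than τ
(default 200 ms, the midpoint of the sensible 100–300 ms range) with the
label of the nearest *following* run of length ≥ τ; at the end of a
recording, where no qualifying successor exists, the nearest preceding
qualifying run is used (a fallback the replacement rule itself leaves
undefined). The procedure iterates to a fixpoint, so no sub-τ run
survives unless the whole timeline is degenerate. Outlier removal treats
`other_high` like any other label and runs after confidence demotion.
`summarizeEvents()` turns the final timeline into labeled intervals with
mean confidences and per-class counts.

# Numerical conventions

Quantiles (IQR everywhere) use R's default type-7 interpolation. All
"exceeds" comparisons in the isolation stage and the gate are strict.
Min–max normalization of a constant signal maps to zeros. The
coefficient-of-variation of a zero-mean norm is reported as 0 with a note.
Every random draw flows from explicit seeds; sub-seeds are derived with a
fixed integer recurrence kept below $2^{31}$.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to exercise every code path
at meaningful statistical power on a single CPU: 200 single-activity
recordings for the isolation and movement-kind checks; a 12-recording,
6-subject corpus (about 570 one-second windows before balancing) for the
5-fold protocol with `desk = TRUE` widths and a 40-epoch cap (the default
corpus converges to its accuracy plateau well before that cap); full
published widths for the architecture-arithmetic checks; and ≥1000 random
fixtures for the exact postprocessing and outlier-removal properties. The
end-to-end evaluation check trains its deployed classifier to convergence
(a single 70/30 split, 150-epoch cap) with dropout lowered to 0.2:
accuracy plateaus early, but the sliding-window evaluator demotes any
window below 95% confidence to `other_high`, so the deployed model needs a
sharp softmax, not just high accuracy — the confidences keep sharpening
for many epochs after the accuracy plateau, and heavy regularization
(dropout 0.5 on a reduced-width network trained on a few hundred windows)
keeps them permanently soft. The default dropout for the accuracy
protocol stays at 0.5.

# Known limitations

* The synthetic generator is the only bundled data source; all quantitative
  results in the test suite and acceptance script describe performance on
  it, not on real athletes.
* Orientation is static: gravity stays on one axis per location, so
  methods that would exploit or suffer from orientation change are not
  exercised.
* The recurrent-only models are slow in this R engine (sequence length
  500) and are validated for correctness, not trained at scale.
* `movementKind()` is computed once per recording; recordings mixing
  periodic and explosive movements use a single threshold multiplier for
  isolation (per-interval re-classification would require a segmentation
  before the segmentation).
* The isolation threshold is a multiple of the whole-recording mean norm,
  which suits the per-trial, one-activity-per-recording setting the
  procedure was designed for. In long mixed sessions an intense activity
  (a sprint) raises the mean enough that a gentler sustained one (a jog)
  hovers near the threshold and fragments into sub-intervals; whole-session
  analysis should rely on the gated sliding-window evaluator instead, whose
  per-window statistic does not depend on the rest of the recording.
* Windows straddling an activity onset are outside the training
  distribution (training windows come from inside labeled intervals), and
  the classifier is occasionally confident on them; a confident mislabel
  there can displace a detected event's onset by up to roughly the window
  length, because best-score postprocessing lets the mislabeled window win
  its whole span and a run longer than τ survives outlier removal. Event
  labels are robust to this; onset timing, occasionally, is not.
* No streaming inference: a recording is evaluated in memory.
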