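---
title: "Methods: PPG quality classification with CNN-LSTM, CNN-MLP and CNN-KAN models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPG quality classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgqc)
```

## The problem

A photoplethysmogram (PPG) records blood-volume changes in microvascular
tissue as a quasi-periodic waveform, one pulse per heartbeat, with a main
systolic peak and a smaller dicrotic bump. Hand-held and wearable devices
sample it continuously (here: 512 Hz, 5-second segments), but a large
fraction of segments is corrupted by motion, ambient light, pressure changes
or sensor saturation. Vitals extracted from corrupted segments are
unreliable, so the segments must be triaged first. `ppgqc` treats this
triage as supervised binary classification: segments labelled 1 (good,
little interference) against segments labelled 2 or 3 (fair/poor), the
latter two merged into a single negative class. Class 1 maps to binary
label 1 throughout.

## Synthetic data: what it emulates and what it does not

Because clinically labelled PPG recordings are proprietary, the package
ships a generator whose output has the statistical structure the
classifiers must separate.

*Clean morphology.* Each beat is the sum of two Gaussians: a systolic bump
of amplitude 1.0 (peak at 25% of the beat period, width 6% of the period)
and a dicrotic bump of amplitude 0.3 at 55% of the period (width 9%). This
reproduces the characteristic double-hump PPG shape without a hemodynamic
model. Each beat period is jittered independently by ±3% (uniform) so the
signal is quasi- rather than strictly periodic; heart rates are drawn from
55–95 bpm in dataset generation. With these widths the spectral fundamental
dominates all harmonics, so rate estimation behaves as it does on real PPG.

*Corruption modes.* Four artifact channels, all scaled by the clean
signal's peak-to-peak range so strengths are meaningful after rescaling:
additive white Gaussian noise (`noise_sd`), a respiratory-band sinusoidal
baseline wander (`wander_amp`, `wander_freq`), motion spikes placed by a
Poisson process (`spike_rate` per second, biphasic exponential shape with a
15 ms time constant, random sign), and symmetric saturation clipping at
`clip_fraction` of the dynamic range.

*Class definitions.* The quality classes are fixed, chosen once to mirror
the verbal grading "little interference / moderate noise / heavy noise":

| class | noise_sd | wander | spikes | clipping |
|---|---|---|---|---|
| 1 good | 0.02 | — | — | — |
| 2 fair | 0.15 | 0.25 @ 0.3 Hz | — | — |
| 3 poor | 0.40 | 0.50 @ 0.25 Hz | 1.5/s, amp 1.5 | 0.8 |

A single global seed expands to per-signal seeds through a counter, so
generation is reproducible and order-independent.

*What passing tests do not show.* The synthetic classes are cleanly
separated by construction — there is no label noise, no inter-subject
morphology variation, no arrhythmia, and the artifact taxonomy is a
simplification. Test AUCs near 1.0 on this data demonstrate that the
models, gradients and training loop work, not that the architectures would
reach any particular accuracy on manually labelled device data, where class
boundaries are far blurrier. The synthetic class boundaries must not be
read as equivalent to manual labels.

## Preprocessing

Four stages, applied in order:

1. **Anti-aliased downsampling.** Default 512 → 128 Hz (factor 4). An
   8th-order zero-phase Butterworth low-pass at 80% of the output Nyquist
   precedes decimation, so peak/trough timing of sub-Nyquist content is
   preserved. The factor-4 default keeps the post-decimation Nyquist
   (64 Hz) above the 50 Hz filter cutoff, so the next stage remains
   realizable.
2. **Moving average.** Centred window, truncating at the edges so length
   is preserved. Default 5 samples at 128 Hz (≈39 ms): smooths sample
   noise without flattening the ~0.1 s systolic peak. The window is a
   tunable and must stay well below the peak width.
3. **Butterworth low-pass.** Default order 4, cutoff 50 Hz, applied
   forward–backward (zero-phase) by default so peak timing is not
   distorted; single-pass filtering is available
   (`zero_phase = FALSE`), in which case the gain at the cutoff is the
   textbook 1/√2. Filters are designed by bilinear transform with
   prewarping, so the cutoff gain is exact; far above the cutoff the
   digital response falls off faster than the analog prototype (frequency
   warping), noticeably so when the cutoff is a large fraction of Nyquist.
4. **Min-max scaling**, per signal, to [0, 1]. Per-signal (rather than
   dataset-global) scaling makes every segment contribute on the same
   scale regardless of sensor gain. A constant segment has no dynamic
   range: it maps to the lower bound with a warning instead of dividing
   by zero.

Only stage 1 changes the segment length; stages 2–4 are length-preserving.

## The classifiers

All three families share the structure: 1-D convolutional feature
extraction, a family-specific temporal/feature reduction, and a scalar
score mapped through a sigmoid to the probability of the good class.

* **CNN-LSTM**: conv stack → batch normalisation → LSTM → global average
  pooling over time → fully connected stack → sigmoid. Selected
  hyperparameters: kernel 15, LSTM hidden 56, feed-forward [112, 64].
* **CNN-MLP**: conv → max pooling (window 4) → channel average → dense
  stack with ReLU hidden activations, hidden sizes [100, 50, 25, 10] →
  sigmoid.
* **CNN-KAN**: the same trunk as the MLP feeding a two-layer
  Kolmogorov–Arnold stack `feature_len → 80 → 1`. KAN layers carry the
  learnable activations on edges: `out_j = Σ_i φ_{j,i}(x_i)` with no fixed
  output nonlinearity. The final scalar is passed through a sigmoid inside
  the loss so binary cross-entropy stays well defined — the KAN itself has
  no a-priori output activation.

### Completing the published layer sizes

The source architectures specify kernel size, LSTM hidden size,
feed-forward widths and KAN grid/order/width, together with total trainable
parameter counts (456,865 / 22,526 / 127,206), but not the convolution
channel counts, depth, or directionality. The defaults of
`model_config()` fix one completion that reproduces all three counts
exactly:

* `cnn_lstm`: conv 1→224 (k15) → conv 224→112 (k15) → batch norm without
  trainable affine terms → 2-layer unidirectional LSTM, hidden 56, one
  bias vector per layer → GAP → FC 56→112→64→1;
* `cnn_mlp`: conv 1→3 (k9) → pool 4 → channel average (158 features) →
  dense 158→100→50→25→10→1;
* `cnn_kan`: conv 1→62 (k12) → pool 4 → channel average (157 features) →
  KAN 157→80→1 where each edge carries G+k = 8 spline coefficients plus a
  residual base weight and a spline scaler (the parametrization used by
  the widely adopted public KAN implementations).

This completion is not unique — several integer solutions reproduce the
counts — and was chosen for coherence: input length 640 matches the
preprocessing default, the recurrent family has a halving channel
progression (224 → 112 → 56), and the KAN per-edge layout matches common
practice. Counting includes only trainable tensors; batch-norm running
statistics are buffers.

### KAN layers and B-splines

Activations live in the spline space of `grid` uniform intervals and
degree `degree` over a fixed domain, with clamped (degree-fold repeated)
end knots; the space dimension is `n_basis = grid + degree`. Bases are
evaluated by a vectorised Cox–de Boor recursion; derivatives use the
standard lower-degree identity. Properties maintained (and tested):
non-negativity, partition of unity, local support over k+2 knots.

Design choices where the design was open:

* *Bare layers vs. model layers.* `kan_layer()` defaults to the pure
  spline combination — activation = Σₘ cₘ Bₘ(x) — with the residual base
  function (`w·silu(x)`) and per-edge scaler behind `include_base`,
  default off. The `cnn_kan` model family turns `include_base` on by
  default because the published parameter count implies that
  parametrization (and the base path keeps gradients alive when an input
  leaves the spline domain).
* *"Order" convention.* The order hyperparameter is interpreted as the
  polynomial degree k (so grid 3, order 5 gives 8 basis functions).
* *"Width" convention.* Width is the hidden-layer size of the KAN stack
  (standard KAN usage), not the number of basis functions; the two
  readings conflict in the source material and the basis count is already
  determined by grid + degree.
* *Domain and clamping.* Activation inputs are clamped to the domain
  boundary rather than extrapolated (the representation theorem is a
  bounded-domain statement); clamped points contribute zero input
  gradient, while the base path still carries gradient. Bare spline specs
  default to [0, 1] (min-max scaled inputs); inside the `cnn_kan` model
  each KAN layer is preceded by a parameter-free batch normalisation, its
  inputs are approximately standard normal, and the model default domain
  is [−3, 3]. Without this normalisation the trunk activations drift
  outside any fixed domain and the spline path saturates.
* *Initialisation.* Spline coefficients and base weights are drawn
  i.i.d. N(0, 0.1²), seeded; scalers start at 1. Small initialisation
  keeps early outputs near zero (probability ≈ 0.5).
* Dynamic grid refinement/extension during training is deliberately not
  implemented.

### Numerical notes

* Early stopping counts *strictly* lower validation loss as improvement;
  ties do not reset the patience counter. The checkpoint is the epoch of
  minimum validation loss.
* BCE clips probabilities to [1e−7, 1 − 1e−7]; the gradient at the score
  is the standard (p − y)/N.
* Thresholded metrics use cutoff 0.5 by default; a ratio with zero
  denominator (e.g. precision with no positive predictions) returns 0
  with a warning.
* ROC AUC integrates the empirical curve trapezoidally over distinct
  score thresholds, which equals pairwise positive-over-negative counting
  with ties scored one half.
* Grid-search ties are broken by fewer trainable parameters, then by
  enumeration order; one seeded training run per configuration.
* Learning rate 1e−3 and batch size 32 (Adam defaults at this data
  scale); both configurable.
* Max pooling uses non-overlapping windows (default 4); gradient is
  routed to the within-window argmax.
* LSTM: coupled single bias per layer, forget-gate bias initialised to 1,
  gates in input/forget/cell/output order; bidirectional stacks run the
  same recursion on reversed time and concatenate.
* All generator, split, initialisation and optimisation randomness passes
  through one seed; two runs with the same configuration are identical.

## Training protocol and problem sizes

The study protocol is: stratified 40/30/30 train/validation/test split,
Adam on BCE for at most 200 epochs with patience 50, model selection by
validation AUC. The packaged experiments run this protocol at desk scale:
the end-to-end checks train *compact* members of each family
(`compact_config()`: 8–16 hidden units, strided first convolution for the
recurrent family) on 600 synthetic segments (300 good / 150 fair /
150 poor) for at most 50 epochs — sizes chosen so a full three-family run
completes in about a minute on one CPU while still exercising every code
path at the published 5 s × 512 Hz segment format. The full-size default
builds are exercised in forward mode and for parameter counting. On the
synthetic benchmark all three families reach test AUC ≥ 0.90 comfortably;
relative ordering between families is data-dependent at this separability
and is reported, not asserted.

## Known limitations

* No real-device adapter is bundled; an import adapter for external
  labelled datasets is a documented extension point (the text dataset
  format is `id,label,fs,s0,s1,...` per row).
* The KAN implementation omits grid adaptation, pruning and symbolic
  readout; it is a classifier component, not a full KAN laboratory.
* Training is single-threaded, dense-matrix R; it is sized for method
  validation and small studies, not for large-scale training runs.
* Bilinear-transform warping makes the digital Butterworth response
  deviate from the analog closed form near Nyquist; comparisons against
  the analog formula are meaningful only when the frequency of interest
  is small relative to Nyquist.
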