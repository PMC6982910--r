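---
title: "Occlusal-force biofeedback analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusal-force biofeedback analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bruxsense)
```

bruxsense analyzes bite-force recordings from piezoresistive sensors
embedded in an occlusal stabilization splint worn by bruxism patients.
This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, and what a green test does and does not establish.

## 1. The simulator: a stated world, not a dial

No public recordings exist for this class of device, so the package
generates its own inputs and every quantitative claim in the test suite
is made *relative to the simulator's stated world*:

* **Six channels at 100 Hz.** Six sensors span the arch; bite-force
  dynamics live well below 50 Hz, so 100 Hz oversamples comfortably.
  (Scaled-down test worlds use 20–50 Hz; the Nyquist margin is retained.)
* **Episodes as a Poisson process.** Clench/grind episodes arrive at
  `episode_rate` events/hour, each lasting 1–6 s, non-overlapping
  (overlapping draws are thinned — a negligible correction at realistic
  rates). The pulse is a raised cosine normalized to attain its labeled
  peak exactly on the sample grid; grind episodes add a 1–2 Hz amplitude
  modulation that still attains the peak at the apex, so labels remain
  exact.
* **Three ordered severity regimes.** Class 0/1/2 have episode rates
  20/60/120 per hour and peak amplitudes 0.4–0.8 / 0.9–1.6 / 1.8–3.0 V
  above a 0.2 V baseline — ordered in both amplitude and rate, inside the
  3.6 V ADC range with headroom. Covariates are linear-in-class means
  with Gaussian jitter, clipped to valid ranges: contact area
  20/35/50 mm² (sd 4), contact points 4/7/10 (sd 1, ≥ 1), pain 1/4/8 on
  a 0–10 ordinal scale (sd 1).
* **Additive i.i.d. Gaussian noise** (default sd 0.05 V) — the regime
  the Donoho threshold targets. Real sensor noise has 1/f components,
  drift, and motion artifacts the simulator does not emulate; a green
  denoising test therefore establishes correctness of the estimator, not
  field performance.

The generator is bit-deterministic given its seed; dataset seeds derive
from a master seed, so collections are reproducible trace by trace.
There is no volts↔newtons calibration anywhere: the hardware paper trail
provides none, so the package works in volts and ADC counts throughout.

## 2. ADC coding

The firmware transfer constants are a 3.6 V reference and 1024 = 2^10
steps: `volts = counts × 3.6 / 1024`, evaluated at 1024 counts → 3.6 V
exactly. Encoding is the floor-quantizing inverse with clamping;
saturated samples return the full-scale count (hardware-faithful) rather
than an error, and windows containing full-scale samples are flagged
`saturated` in session reports. The round-trip error is one-sided:
`decode(encode(v)) − v ∈ (−LSB, 0]`.

## 3. The sleep/wake detector

The detector watches the across-channel maximum count (the "resultant
force" reading of a multi-sensor splint). From SLEEP it wakes after
`debounce_on` = 3 consecutive samples strictly above the threshold; from
ACTIVE it sleeps after `debounce_off` = 3 consecutive samples at or
below it; events separated by fewer than `refractory` samples (default
50 ≈ 0.5 s at 100 Hz) merge. Debounce and refractory are not in the
hardware description — they are the standard guards for the false
positives the threshold exists to avoid, and both are configurable.
Event bounds are half-open (`end` = first sample after the event) so
`duration = (end − start)/rate` holds exactly.

Two properties deserve care:

* **Equality with a brute-force scan.** The run-length implementation is
  equivalent to a per-sample counter machine because any single opposite
  sample resets a debounce counter; the suite checks equality on 1,000
  random traces.
* **Monotonicity in the threshold is a regime property, not a theorem.**
  For *episodic* signals — disjoint unimodal pulses over a quiet
  baseline — each pulse contributes at most one event and its
  supra-threshold interval shrinks as the threshold rises, so the event
  count is non-increasing in the threshold (for thresholds above the
  baseline; at or below it the detector never sleeps and the recording
  is one event). For arbitrary noise-like inputs the property is false
  for *any* run-length detector: raising the threshold can split one
  event into several, exactly as level-crossing counts are non-monotone.
  The tests therefore assert monotonicity on noiseless clench-pulse
  traces with no refractory merging, the regime the detector is designed
  for, and assert oracle-equality (not monotonicity) on arbitrary
  traces.

## 4. Translation-invariant wavelet denoising

The base denoiser `T` is: periodized decimated DWT to `level` scales
(default `min(4, ν₂(n))`, where `ν₂` is the number of times `n` divides
by 2 — periodization needs even length at every stage), soft threshold
of **all** detail coefficients at a single global
λ = σ√(2 ln n) (the universal threshold), inverse transform. Hard
thresholding is available; per-level thresholds are not (the source
material specifies a single "Donoho threshold").

* **Wavelet family:** `db4` (8-tap Daubechies, 4 vanishing moments) by
  default; `haar` and `db2` available. Filter coefficients were
  recomputed from spectral factorization and are property-tested
  (sum √2, unit norm, shift-orthogonality) rather than trusted.
* **σ estimation:** `median(|d₁|)/0.6745` over finest-scale details
  computed **without decimation** (circular convolution with the
  highpass filter). The undecimated variant is exactly invariant under
  circular shifts, which keeps the cycle-spun estimator exactly
  shift-equivariant when σ is estimated from data.
* **Cycle spinning:** `T̄(x) = Ave_h S_{−h} T(S_h x)` over a shift set.
  The full set `{0, …, n−1}` gives exact commutation with circular
  shifts (tested at 10⁻⁸). The default is the **first 32 consecutive
  shifts**, *not* 32 evenly spaced ones: with `n` divisible by
  32·2^level, evenly spaced shifts are all multiples of 2^level, which
  merely permute periodized DWT coefficients — every shifted denoiser is
  identical and nothing spins. Consecutive shifts cover every residue of
  the decimation grid whenever `n_shifts ≥ 2^level`. (This was found the
  hard way; the test suite now pins it.)
* **Boundary handling:** periodic everywhere in the core (required for
  exact shift equivariance). `denoise_trace()` accepts arbitrary lengths
  by reflection-padding to a multiple of 2^level and cropping, which
  sacrifices exactness only at the two ends.

**When does denoising help?** The universal threshold biases every
retained coefficient by up to λ and kills sub-λ detail outright. For a
piecewise-constant signal, each jump spreads energy over ~`filter
length` coefficients per scale, so with an 8-tap filter, n = 256 and
three jumps the bias exceeds the noise reduction (measured: RMSE *worse*
than the noisy input in 98% of seeds — with haar, which matches steps,
it is better in ~100%). At n = 1024 the same three jumps are sparse
enough that single-pass and cycle-spun db4 beat the noisy input in 100%
of seeds, and cycle spinning beats single-pass on average (Gibbs
suppression). The RMSE-benefit tests therefore state their world at
n = 1024; the shift-invariance tests keep n = 256, where invariance is
exact regardless.

## 5. Monitoring statistics and features

Per tumbling window (default 60 s; day- or week-scale monitoring is
composed of windows) and per channel: mean, max, min, population sd,
population variance, and the cross-channel covariance matrix — the
matrix reading is chosen because a scalar "covariance of all bite
forces" adds nothing beyond the variance. Population (1/n) normalization
is used consistently, so `variance = sd²` and `diag(φ) = ψ` exactly; the
final partial window is kept when at least half-length.

The five per-window network inputs are the mean event force, mean event
duration, mean contact area, modal contact points, and the most recent
pain report (carried forward through quiet windows, which are flagged).
Contact area/points and pain are covariates — in the clinic they come
from occlusion paper, T-Scan and patient feedback, not from the voltage
trace — so the pipeline matches detected events to labeled episodes by
interval overlap to fetch them.

Blocks are 16 channels × 128 frames: six per-sensor mean forces, the
five features, five zero channels padding to the network's 16-channel
input width. Both the frame count and the packing are engineering
choices (the source material fixes only the 16-channel input); scaled
test worlds use 32 frames. Channels are standardized by training-split
statistics; near-constant channels get sd 1 so they pass through
untouched.

## 6. The grading network

Stages follow the published plan row for row: Conv1d 16→32, MaxPool,
6 × Bottleneck(32), Conv1d 32→64, MaxPool, 6 × Bottleneck(64), Conv1d
64→128, MaxPool, 6 × Bottleneck(128), Conv1d 128→256, MaxPool, GAP,
FC 256→64, FC 64→3. A bottleneck is an inverted residual:
pointwise-expand (×4) → depthwise (k = 3) → pointwise-project, batch
norm after each convolution, ReLU6 after the first two, linear
projection, identity skip. Unstated internals (expansion 4, kernel 3,
stride 1, MaxPool 2/2, BN ε = 10⁻³) follow the MobileNetV2 conventions
the pwconv/dwconv/ReLU6 vocabulary points to. `width_divisor` scales
internal widths for desk-scale runs; any other width deviation errors
with the offending row. The three output levels map to −0.5 / 0 /
+0.5 mm adjustment altitudes (symmetric, with a no-change middle class);
prediction is the argmax with exact ties resolved to level 1
(no adjustment — the conservative clinical default).

Training is momentum gradient descent (coefficient 0.9), batch 128,
cross-entropy, 80/20 train/test split at the session level, stratified
by class. The learning rate is unpublished: default 0.01 with a ×0.1
decay at ⅔ of the epochs. Everything is seeded: init, shuffling, split —
two runs with the same seed are bit-identical.

Two empirical findings shaped the implementation:

* **Precise BN.** With few training steps, exponential-moving-average
  BN statistics lag the weight trajectory; compounded over ~50 stacked
  normalizations this left inference at chance accuracy while the
  training-mode loss sat below 0.05. The package therefore re-estimates
  inference statistics exactly on the training split with the current
  weights after every epoch (a momentum-1 capture pass). This is the
  "precise BN" practice from the large-batch training literature, and it
  restores inference = training behavior (verified to accuracy 1.0 on a
  separable set).
* **Momentum-SGD loss curves are not monotone.** Strict per-epoch
  monotonicity failed in 30–60% of seeded runs at every learning rate
  from 10⁻⁶ to 10⁻¹ — momentum overshoots produce small upticks by
  construction, while all analytic gradients match numerical
  differentiation to 10⁻⁵ relative. The descent test therefore asserts
  finiteness and net decrease (final < initial epoch loss) across seeded
  runs rather than a property the optimizer does not have.

**What the class-recovery test establishes.** The scaled-down acceptance
run (300 sessions of 120 s, width/4 network, batch 32, 30 epochs)
reaches ≥ 0.9 held-out accuracy with a diagonal-dominant confusion
matrix. The regimes are separable by construction — mean block force
alone nearly separates them — so this is a *parameter-recovery* check of
the full pipeline (simulate → detect → featurize → train → predict), not
evidence about clinical grading performance. Transfer-learning
pre-training on external data is out of scope (no such data exist to
reproduce).

## 7. Pipeline and the feedback loop

`run_session()` runs denoise → encode → detect → window statistics →
features → block → predict and assembles a session report (events,
summaries, features, prediction, threshold audit log, quiet/saturated
flags). Denoising is applied to the analog-domain signal before coding
by default; a `denoise_domain = "digital"` flag moves it after. The two
orders agree within one quantization step per sample on smooth in-range
signals (tested at exactly 1 LSB); this is an empirical sanity bound,
not a theorem — soft thresholding is 1-Lipschitz in ℓ₂, not ℓ∞.

`feedback_step()` implements the remote-threshold loop as a declarative
rule: if the session's event rate exceeds `trigger_rate`, raise the
threshold by `increment` counts (clamped to the ADC range with a
warning), through the audit-logged `update_threshold()`. On a stationary
recording the induced threshold sequence is non-decreasing and bounded,
hence reaches a fixed point; the test drives the loop to convergence.
The vibratory biofeedback wearable itself is out of scope and appears
only as report content.

Reports serialize to JSON with fixed key order and full-precision
numbers, so identical config + seed reproduces byte-identical files —
the determinism contract the acceptance suite checks.

## 8. Serialization and scope notes

All formats are plain text: tidy CSV for traces (with JSON sidecars for
labels/covariates and ADC metadata), JSON lines for events, JSON for
reports, checkpoints and configs. HDF5 appears in the original interface
sketch but no R HDF5 binding is available in the supported environment,
so CSV/JSON are the formats of record. Model checkpoints embed the
network config, the standardizer, and full-precision weights in one JSON
file; a restored model reproduces predictions exactly.

Known limitations: no volts↔newtons calibration; no per-channel event
streams (the resultant-force reading is used, as the aggregate the
hardware thresholds on); no real-time/streaming denoising (cycle
spinning is inherently batch); the simulator's noise model is white and
Gaussian; the classifier's accuracy claims are relative to the
simulator's separable regimes.
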