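---
title: "Relating audio CNN layer activations to salience: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating audio CNN layer activations to salience: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`audsal` implements an analysis pipeline that asks how the activity at
different depths of an audio-classification convolutional network relates
to three views of the same natural soundscapes: their acoustic feature
profile, the salience that human listeners report behaviorally, and the
band-limited energy of concurrent EEG recordings.  Because the original
recordings, listener responses and EEG of such studies are rarely
available, the package pairs every analysis stage with a synthetic
generator that plants a known ground truth, so the whole chain is testable
by parameter recovery.

This vignette records the models, the tunable parameters, and the design
decisions made where the methodology left genuine choices open.

## The network and its activation series

The network is a VGG-style audio classifier: four stages of 3 × 3
same-padded convolutions, each followed by a rectified linear unit and
non-overlapping 2 × 2 max pooling, then fully connected layers of 4096 and
128 units (both rectified) and a linear 4923-way prediction layer.  The
input is a 96 × 64 log-mel spectrogram covering 960 ms.  Six layers are
carried into the analyses, shallow to deep: Pool2 (49,152 outputs), Pool3
(24,576), Conv4 (49,152), Pool4 (12,288), FC1 (4,096) and Embed (128).
Tests assert all six widths exactly; pooling conventions are forced by
these dimensions (stride 2, no padding).

Two choices deserve comment:

* **Weights.** The analysis chain is weight-agnostic: every downstream
  quantity is computed from the activations of whatever network is
  supplied.  The default is He-scaled Gaussian weights with zero biases
  under a fixed seed, which makes every pipeline property (dimension
  bookkeeping, determinism, shift consistency, surprisal recovery)
  testable without a training corpus; `cnn_config(weight_source = "file")`
  accepts a validated `.rds` of trained weights with one named `W`/`b`
  pair per layer.  Training itself is out of scope.
* **Timestamps.** An activation frame carries the END time of its 960 ms
  window, so surprisal at time *t* uses only audio up to *t* and the
  history comparison below stays causal.

The mel front end resamples audio internally to 16 kHz, where the 25 ms
window and 10 ms hop are integer sample counts (400/160) and a 960 ms
segment yields exactly 96 frames (`floor(n/hop)` with half-window
reflection padding).  64 triangular mel filters span 125–7500 Hz; log
power is floored at 1e-10 so digital silence is well defined.  Activation
series slide this window in `hop_s = 0.1` s steps (10 Hz), matching the
rate at which all signals are later compared.

## Network surprisal

For each layer, surprisal at frame *t* is the Euclidean distance between
the activation vector at *t* and the element-wise mean of the activation
vectors in the strictly preceding `history_window_s = 4` s.  A constant
pattern gives zero; a sustained step gives a spike that decays to zero as
the history window refills.  Frames with less than `min_history_s = 1` s
of history are `NA`; frames with between 1 and 4 s use the history that
exists (the conditioning step later drops the first 2 s anyway).  The
distance is taken on raw flattened activations without dimensionality
normalization: cross-layer comparisons are made through correlations,
which are scale-free, and surprisal itself is scale-equivariant (tested).

## Signal conditioning

All continuous series — surprisal, feature tracks, salience, band
energies — pass one chain before correlation: resample to 10 Hz
(linear interpolation), truncate to 120 s, drop the first 2 s, high-pass
at 1/30 Hz and low-pass at 1/6 Hz, both order-4 Butterworth applied
forward–backward (zero phase, so filtering adds no hidden lag to the
explicit lag search).  Truncation is applied before trimming; the interior
samples are identical either way.

Zero-phase filtering at a 1/30 Hz cutoff on a ~2 min series is numerically
delicate: naive forward–backward filtering leaves edge transients of order
30% of the signal.  `audsal` therefore matches steady-state initial
conditions and pads both ends with an autoregressive (Burg) extension of
the signal, sized so the slowest filter pole decays to 0.1%.  Constants
and sinusoids extend exactly, and the measured response reproduces the
Butterworth magnitude closed form $|H|^2 = 1/(1+(f/f_c)^8)$ to about
1e-4 (DC rejection > 99.99%, 0.5 Hz attenuation > 99.9%).

One caveat is documented rather than engineered away: conditioning is only
idempotent for in-band content.  Energy on the Butterworth shoulders is
attenuated again on every pass — for broadband input the closed-form RMS
ratio of a second pass is $\sqrt{\sum G^4 / \sum G^2} \approx 0.91$ —
so the idempotence test uses in-band signals (~1% RMS change).

## Lagged correlation and event windows

`max_lagged_correlation()` computes the Pearson correlation on the
overlapping region at every integer-sample lag within ±3 s and returns the
maximum with its lag; positive lag means the second series follows the
first.  Each lag's overlap is standardized per-lag (an open choice; the
alternative global standardization differs negligibly at these lengths and
is noted here as the road not taken).

Event-locked comparison correlates surprisal in ±3 s windows around each
salient event with the salience curve shifted by a fixed motor delay of
1.4 s — the delay of the behavioral report, reused by the generator as
its ground-truth motor delay.  Events whose windows leave the series are
skipped and counted.

## Behavioral salience and event detection

Salience is the percentage of subjects attending at each 10 Hz sample.
Salient events are peaks of the smoothed derivative of this curve; the
smoother is the same three-pass, five-sample moving average used for
feature slopes.  Design choices the source methodology leaves open:

* Derivative peaks below 0.5 SD of the derivative are ignored (noise
  floor; configurable) — this prevents micro-peaks from flooding the
  candidate set.
* Event strength is an *equally weighted* sum of the z-scored slope height
  and the z-scored curve maximum in the 4 s after the event; the weights
  are exposed as arguments since the combination is stated but not
  quantified in the source protocol.
* The strongest 50% of candidates are retained
  (`keep_fraction = 0.5`, count `ceiling(keep_fraction * n)`); this cut is
  an event-selection protocol for the downstream event-based analyses.
  Detection *sensitivity* (planted-event recovery) is therefore measured
  against the full candidate set: with few spurious peaks, keeping the top
  half would cap measurable recovery near 50% no matter how good the
  detector is.
* Categories are taken from the nearest ground-truth annotation (synthetic
  scenes) or an annotation file (real data).

## Layerwise statistics

`layer_trend()` regresses a per-layer metric (with replicates pooled) on
the layer index 0–5 and reports the slope, its t statistic, residual
degrees of freedom, p value and 99% CI.  Pooling replicates mirrors the
large degrees of freedom such analyses report.

`cumulative_variance()` implements sequential residual regression: the
target (salience, or a concatenation of delayed event windows) is
regressed on the shallowest layer's surprisal; the cumulative variance
explained after layer *k* is $1 - \mathrm{var}(r_k)/\mathrm{var}(y)$, and
the residual becomes the target for the next layer.  Each regression is
simple (one predictor), per the stated procedure; the sequence is
provably non-decreasing and bounded by 1, and an orthogonal two-component
construction recovers 0.5 then 1.0.  `random_baseline()` repeats the
procedure with every layer after the first replaced by seeded standard
normal series; the expected chance increment per random layer is
$1/(n-1)$ of the remaining residual variance, which the tests check
against the analytic value.

`compare_groups()` contrasts two conditions (e.g. dense vs sparse scenes)
per layer and tests early (Pool2–Conv4) against deep (Pool4–Embed) mean
differences with a two-sample pooled-variance t test on the three-vs-three
per-layer differences (4 degrees of freedom, matching the df convention of
the reported analyses; a paired test would give df 2).

## Event prediction

Feature slopes are first differences (units/s) smoothed by three passes of
a centered equally weighted moving average; the window is 5 samples at
10 Hz, exposed as configuration since only the *number* of passes is
specified by the protocol.  Overlapping 2 s bins advance by 0.5 s; a bin
is labeled 1 exactly when an event onset falls inside it (onset
membership, not event extent).  Before binning, each predictor can be
lag-aligned to the salience curve within the same ±3 s range used by the
correlation analyses.

The classifier is a two-class linear discriminant with pooled within-class
covariance, written in the package so the protocol is explicit: seeded
*stratified* five-fold assignment (per-fold class counts within one of
equal), held-out scores pooled across folds, threshold sweep over the
pooled scores for the ROC, AUC as the Mann–Whitney statistic (ties count
one half).  A singular pooled covariance is ridge-regularized with epsilon
1e-6 times the mean diagonal, with a warning.  Tests cross-check the
discriminant direction against `MASS::lda` and the AUC against `pROC`.

## The synthetic study

The generator emulates the statistical structure of a dichotic-listening
salience study, not its content:

* **Scenes** are 1/f background noise plus parametric event tokens of five
  categories (speech-like harmonic complexes with a pitch glide and 4 Hz
  syllabic modulation; note sequences; vibrato vocalizations; band-limited
  vehicle swells; impulsive tapping bursts).  Sparse scenes plant 3
  events/min, dense scenes 9/min (three times the sparse rate, the
  package's convention for the unquantified sparse/dense distinction).
  Events are uniform in time with ≥ 1 s separation, −15 to −9 dB re unit
  RMS against a −30 dB background, 0.5–1.5 s long.
* **Listeners** are two-state (attend/ignore) Markov chains at 10 Hz:
  baseline switch-to-attend probability 0.05/s, leave probability 0.2/s,
  and a ×(1 + event_gain) boost of the switch probability in the 1 s
  window starting 1.4 s (the motor delay) after each event;
  `event_gain = 30` is the documented high-gain setting under which ≥ 80%
  of planted events are recoverable.  The source studies do not model
  subjects at all — this is the minimal process that produces a
  percentage-attending curve with event-locked derivative peaks.
* **Band energies** are generated directly at 10 Hz as
  weight × lag-shifted driver + Gaussian noise, z-scored, with the weight,
  lag and noise stored as ground truth; a raw multichannel
  sinusoid-plus-noise generator additionally exercises the spectral
  band-energy path at 256 Hz.

What the generator does *not* emulate: semantic content, reverberant
acoustics, inter-subject heterogeneity, EEG artifacts (ocular, line
noise — inputs to the EEG module are assumed pre-cleaned), and any
relationship between scene acoustics and EEG beyond the planted one.
Passing recovery tests therefore demonstrates that the measurement chain
is faithful — not that the scientific conclusions transfer to real
recordings, whose headline statistics depend on data that is not
deposited.

The standard benchmark study used by the tests and by
`scripts/acceptance.R` is 6 scenes × 30 s × 20 subjects.  Thirty-second
scenes keep the full-size CNN forward pass (the costly stage: ~0.8 GFLOP
per window, 291 windows per scene) comfortably inside a few minutes while
leaving 28 s of conditioned 10 Hz signal per scene, ample for the
trend-recovery statistics; 20 subjects matches typical behavioral cohort
sizes.  The planted layer profile declines linearly from weight 1.0
(Pool2) to 0.2 (Embed) with noise SD 0.6 and lag 0.5 s; recovery is
declared when `layer_trend()` on the measured max-lagged correlations
returns a negative slope.

## EEG module choices

Band energy uses 1 s Hann-tapered windows advanced by 100 ms; per band,
*power* (not amplitude) is averaged over the FFT bins inside the band —
the averaging domain is unstated in the protocol and power is the
convention adopted here.  The six bands are Delta (1–4 Hz), Theta (4–7),
Alpha (8–15), Beta (15–30), Gamma (30–50) and High Gamma (70–110); a
sampling rate below twice a band's upper edge is rejected naming the band.
Each channel × band track is z-scored over the scene.  Electrode groups
(e.g. 21 electrodes near Fz as "frontal", 23 near Cz as "central") come
from a configurable mapping file; no cap layout is hard-coded.

## Numerical notes and known limitations

* Linear-interpolation resampling is used throughout (22.05 kHz → 16 kHz
  audio; arbitrary → 10 Hz series).  At these ratios the aliased energy is
  far below the features' discrimination thresholds; a polyphase
  resampler would be the next refinement.
* The first defined surprisal frame sits at 1.96 s (window end 0.96 s +
  1 s minimum history); placing surprisal on the scene's absolute 10 Hz
  grid extends the first defined value backward, and conditioning then
  discards those first 2 s.
* Mel-spectrogram edge frames use reflection padding and are spectrally
  smeared; shift-consistency and tone-concentration properties hold for
  interior frames.
* Roughness is computed from the magnitude of the analytic signal
  (Hilbert envelope), mean-removed, with the modulation spectrum averaged
  over 30–150 Hz and normalized by frame RMS.  The envelope method is an
  open choice of this implementation; the normalization makes the measure
  amplitude-invariant, and a silent frame has roughness 0 by definition.
* Acoustic feature formulas follow standard definitions of the named
  quantities (RMS loudness in dB, spectral centroid/spread/flatness,
  normalized successive-difference irregularity, autocorrelation pitch and
  harmonicity, modulation-centroid rate and scale); exact equivalence to
  any particular prior feature toolbox is not claimed.
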