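---
title: "Detecting single microperimetry flashes from occipital EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single microperimetry flashes from occipital EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashvep)
```

## The problem

Microperimetry (MP) maps localized retinal sensitivity by flashing small
stimuli of graded luminance while the patient presses a button. The test is
therefore only as reliable as the patient's subjective responses. `flashvep`
implements and stress-tests an objective alternative: deciding, from a short
occipito-parietal EEG recording, whether a given 600-ms window contains the
cortical response to a single 200-ms flash. This is a hard regime for
classical visual-evoked-potential (VEP) analysis — one presentation per
location (no averaging), a long flash rather than a brief or flickering one,
and, when stimulus timestamps are recovered offline from screen video,
synchronization uncertainty of up to 250 ms.

The pipeline is: common median re-referencing, 4–49 Hz band-pass filtering,
per-channel z-scoring, offset-locked segmentation into 600-ms stimulus and
non-stimulus windows, and a stacked two-layer bidirectional LSTM that labels
each window. Because no public recordings exist for this acquisition setup,
the package ships a ground-truthed synthetic generator that emulates the
study conditions, so every stage — and the whole chain — is testable
end-to-end.

## The synthetic generator

`sim_config()` fixes the acquisition conditions: 250 Hz sampling; the
8-channel montage P3, P4, PO3, PO4, POz, O1, O2, Oz; 200-ms flashes
separated by uniform 2–3 s gaps; stimulus intensity on the device dB
attenuation scale (0 dB = 127 cd/m², tenfold attenuation per 10 dB, 20 dB =
the 1.27 cd/m² background); and a one-sided uniform error of up to 250 ms on
logged offsets, because offline video annotation always observes the offset
late. A symmetric jitter variant exists for sensitivity analyses.

Design choices where the acquisition literature gives no equation:

* **Evoked template.** A sum of Gaussian-windowed deflections — by default
  N75 (−2 µV), P100 (+5 µV), N135 (−3 µV) with 20–30 ms widths — chosen for
  parsimony and differentiability; the whole response sits well inside
  300 ms of flash onset.
* **Intensity → amplitude.** Cortical response amplitude compresses with
  luminance; we use `(L(dB)/L(0))^0.3`. The exponent is exposed in the
  config; nothing downstream depends on its exact value, only on
  monotonicity.
* **Topography.** Per-channel gains are occipital-dominant (O1 = O2 = 1,
  Oz = 0.8, parieto-occipital ≈ 0.35–0.4, parietal = 0.2). Gains were chosen
  so that channels do not tie at the per-sample median, which would zero a
  channel after re-referencing in noise-free tests.
* **Background.** 1/f activity synthesized by spectral shaping of white
  noise (slope 1, SD 1.5 µV), an amplitude-modulated 10 Hz alpha rhythm
  (SD 1 µV), blink-like biphasic transients applied *identically to all
  channels* (so they exercise common-mode rejection), and channel-local
  high-frequency muscle bursts. Absolute single-trial VEP amplitude in µV is
  unknowable from the published material; the SNR implied by these defaults
  is a free parameter and is flagged as such here. `sim_config_high_snr()`
  rescales the template so its peak is 5× the background SD — the regime
  used for parameter-recovery experiments, not a claim about real data.
* **Schedule feasibility.** Gaps are drawn uniform on `isi_range`, truncated
  from above so the remaining flashes always fit in the configured duration
  at minimum spacing (feasibility is `duration ≥ n·(flash + min gap)`).
  Without truncation, realistic trial lengths (e.g. 39 flashes in 92 s)
  would be infeasible under a plain uniform 2–3 s gap model.
* **Times vs samples.** Event times are stored in seconds; sample indices
  are derived by half-up rounding at the point of use.

The noise stream is seeded independently of the evoked-response parameters,
so a run with zero amplitudes is an *exact* noise-only reference: recording
minus reference equals the sum of injected scaled templates to machine
precision. The test suite asserts this superposition audit, along with
bit-identical regeneration from a config and bounded jitter over 10⁴ draws.

What the generator does **not** emulate: volume conduction from a head
model, eye movements and fixation behavior, pupil dynamics, non-stationary
noise floors, or electrode drift. Passing recovery tests on this generator
therefore demonstrates that the pipeline can extract a time-locked response
under the stated timing and SNR conditions — not that real recordings reach
any particular accuracy.

## Preprocessing

The chain is fixed — common median reference (CMR), then band-pass, then
z-score — and `preprocess_recording()` deliberately exposes no reordering.

* **CMR** subtracts the per-sample median across all recorded channels.
  With eight channels the median is the mean of the 4th and 5th order
  statistics. The median of the output is exactly zero at every sample, and
  any common waveform is rejected exactly; both are asserted in tests.
* **Band-pass** is an order-4 digital Butterworth, 4–49 Hz. Application is
  zero-phase (forward–backward) by default because the analysis is offline
  and peak latencies matter; this squares the magnitude response, and the
  time-domain gain is checked against the analytic `|H(f)|` at 10 and 60 Hz.
  A causal single-pass mode exists, in which "order 4" is the literal
  transfer-function order. Edges are protected by odd-reflection padding of
  one settling length (three cycles of the 4 Hz edge); the convention is
  stated here because it is otherwise invisible.
* **Z-scoring** is per channel over the whole recording, population
  (divide-by-n) convention, applied before segmentation. Per-segment
  normalization is deliberately not the default. A constant channel is an
  error that names the channel.

## Segmentation

Each flash contributes one stimulus window: the 150 samples (600 ms at
250 Hz) ending at the *logged* offset, half-open `[offset − window, offset)`
with `start = round(offset·fs) − 150`. Logged — not true — offsets are used
so the classifier faces the same synchronization-limited regime as the
acquisition; true offsets are kept in the manifest for diagnostics. The
remaining signal, including the recording head and tail, is tiled
left-to-right into 150-sample non-stimulus windows; a trailing partial chunk
is zero-padded at its tail and kept only if at least 25% of it is real
signal, so near-empty padded windows cannot inflate the majority class.
Windows closer together than 600 ms are an error; events whose window falls
outside the recording are dropped with a warning. Segment counts and
boundaries are verified against an independently written brute-force tiler
over random schedules. Class-wise averages (`average_segments()`) exclude
padding via per-point counts rather than averaging zeros.

## The classifier

Each segment enters as a 150-step sequence with one feature per selected
channel. The model is two stacked bidirectional LSTM layers with dropout
after each, and a single sigmoid unit on the concatenated final hidden
states of the two directions of layer 2; the loss is binary cross-entropy.
Training uses mini-batch ADAM (batch 8), early stopping on validation loss
with the best-validation weights restored. The forward/backward passes and
full backpropagation through time are implemented in compiled code, batched
across the mini-batch at each timestep; gradients are verified against
central finite differences to 10⁻⁴ relative error in the test suite.

Hyperparameters the acquisition literature does not pin down were set to
small-data conventions and are all exposed in `train_config()`: 32 hidden
units per direction (sized so that a full trial's fit takes seconds on one
CPU), dropout 0.3, learning rate 10⁻³, at most 100 epochs with patience 10,
decision threshold 0.5. There is no class weighting by default — the
observed majority-class bias in this regime implies none was used — but a
`class_weight` option implements per-example loss weighting for
cost-sensitive variants.

Splitting is stratified per segment at 70/15/15 with exact
largest-remainder apportionment per class, shuffled under a seed. Whether
the original splits were per-segment or per-stimulus-block is not decidable
from the published description; stratified per-segment is the default and a
chronological mode is available. Both O1 and O2 enter as two features per
timestep (feature-per-channel), not concatenated in time.

## Evaluation

Stimulus is the positive class. `compute_metrics()` reports accuracy,
precision, sensitivity, specificity, F1 and Cohen's kappa on the percent
scale (kappa ×100, matching how such tables are printed). Metrics with zero
denominators are `NA`, never 0 — a predictor that never says "stimulus"
must not silently score perfect precision. Values are rounded half-up to
2 dp only at the reporting boundary; all internal comparisons use unrounded
values. `infer_confusion_from_metrics()` inverts a printed
(precision, sensitivity, specificity) triplet to the smallest integer
confusion matrix consistent with it (ties broken lexicographically by
`tp, fp, fn, tn`), which lets the arithmetic of published rows be checked
exactly; the half-up rounding convention was verified self-consistent for
every reconstructed row.

## Experiments

`run_trial()` executes the full chain. CMR always uses all eight recorded
channels, as acquired; the montage then subsets the *preprocessed* channels
before segmentation and classification (a pre-CMR subset mode exists for
ablation). `run_montage_comparison()` evaluates every montage on the same
simulated recording, the same segments and the same splits per seed,
retraining from scratch per montage — isolating the montage effect. Every
stage draws from a disjoint seeded stream derived from one master seed, so
results regenerate bit-identically.

## Problem sizes and what the recovery experiments show

The recovery experiments in the test suite use: five seeds of a high-SNR,
zero-jitter trial at full scale (190 s, 75 flashes, O1/O2), where the median
held-out balanced accuracy must reach 0.90; and five-seed grids at the scale
of the shorter recorded trials (92 s, 39 flashes) for the degradation
checks — seed-averaged balanced accuracy must be non-increasing as jitter
grows 0 → 250 ms and as the stimulus dims from the high-intensity (4 dB) to
the low-intensity (16 dB) setting with the template amplitude held anchored
at the high-intensity calibration. The montage experiment uses the same
small scale and requires mean O1/O2 accuracy to exceed P3/P4 under the
occipital-dominant topography. Recovery fits use 24 hidden units, at most
25 epochs and patience 4; these sizes were chosen so the whole suite runs
on one CPU in minutes and are stated here as the package's experiment
design. Degradation grids run at zero-to-configured jitter with everything
else identical, so the comparisons are paired.

## Known limitations

* The generator's SNR defaults are assumptions, not measurements; absolute
  accuracies on synthetic data say nothing quantitative about real EEG.
* The BiLSTM is trained and tested within one simulated trial, mirroring
  the within-trial protocol it emulates; cross-trial generalization is out
  of scope.
* No ICA or regression artifact removal, no notch filter, no bad-channel
  interpolation — the preprocessing chain implements exactly the three
  stated steps.
* EDF I/O is not provided; recordings are read and written as labeled CSV,
  events as TSV, configurations as YAML.
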