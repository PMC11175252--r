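---
title: "Measuring jump height from sound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring jump height from sound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A countermovement jump (CMJ) is the standard field test of lower-limb power.
Its outcome measure, jump height, follows from the flight time $t$ between
take-off and landing under uniform gravity:

$$h = \frac{g\,t^2}{8}, \qquad g = 9.81\ \mathrm{m/s^2}.$$

Timing instruments (contact mats, photocell gates, high-speed video apps)
all reduce to estimating $t$. Audio is an attractive alternative: a
smartphone microphone placed near the athlete's feet records a quiet
take-off transient (a strip of adhesive tape on the sole peeling off at
push-off) and a much louder landing impact. In quiet rooms, energy
thresholds on the waveform suffice; in a working gym — 70–90 dBA of music,
voices, bouncing balls, and dropped weights — they do not. `soundjump`
detects the two events with a pair of binary convolutional networks that are
robust to such interference, refines each detected event to a precise onset,
and converts the flight time to height.

Because jump-height errors scale as $\mathrm{d}h = g\,t\,\Delta t/4$, a
7 ms flight-time error at a typical 495 ms flight (a 30 cm jump) moves the
height estimate by only 8.5 mm — the accuracy scale this pipeline targets.

## Front-end representation

The canonical signal is mono, 48 kHz, amplitudes in $[-1, 1]$. The front-end
computes a 128-band Mel spectrogram with an 800-sample (16.7 ms) Hann
window and 400-sample hop (50% overlap), in decibels referenced to the
clip's maximum band power with a $-80$ dB floor. Two derived channels — the
per-band regression slope over a $\pm 2$-frame neighborhood (delta) and its
second application (delta–delta) — are stacked as an RGB-like third
dimension: they carry the velocity and acceleration of spectral change,
which is exactly what distinguishes an impulsive event from steady
background.

The nominal hop of a 16.7 ms window at 50% overlap is 8.33 ms; twelve hops
tile 100 ms exactly, which is why the classifier input is a 12-frame
segment: jump transients last 50–80 ms, so every event fits inside one
segment with margin.

Standardization is per-channel and global (one mean/sd per channel,
estimated on the training split and stored with the model). A clip at
inference is always standardized with the *stored* statistics, never its
own — otherwise a loud clip would silently re-scale itself into a different
distribution than the detectors were trained on.

## Detector architecture and training

Each of the two detectors (landing, take-off) is a small CNN over
$128 \times 12 \times 3$ segments: three convolutional blocks of 16, 32 and
64 filters (each block: $3\times3$ conv + ReLU, batch normalization,
$3\times3$ conv + ReLU, dropout 0.25, $2\times2$ average pooling), a
flatten, a 768-unit dense layer with PReLU followed by dropout and batch
normalization, a 64-unit linear layer, and one sigmoid output — about
911,000 trainable parameters. The $3\times3$/$2\times2$ sizes are the
smallest standard choices that let the 12-frame axis survive three poolings
($12 \to 6 \to 3 \to 1$). `build_detector()` guards the parameter count
([8e5, 1.05e6]) so that architectural edits cannot silently change the
model class; deliberately small test networks relax the guard via
`detector_spec(param_range=)`.

No deep-learning framework is involved: convolution and pooling kernels are
compiled code (`src/convnet.cpp`, im2col + BLAS), and the layers, Adam
optimizer, and binary cross-entropy loss are plain R. The test suite
verifies every analytic gradient against central finite differences.

Training follows the reference protocol: batch size 64, Adam with learning
rate 0.01, binary cross-entropy, an 80/10/10 train/test/final split, early
stopping monitoring *precision* on the test split (patience 10 under the
100-epoch default). Precision is the right monitor because a false landing
triggers the whole downstream pipeline, whereas a missed one merely skips a
trial. Ties in precision are broken by recall when restoring the best
weights, so a perfect-precision/low-recall epoch does not freeze an
under-sensitive model. Two binary networks are used instead of one
three-class network: the landing is the louder, more reliable event, so it
serves as the trigger, and the take-off detector then only examines the
physiologically possible window.

The training pool keeps every positive segment and a small per-recording
set of negatives: the highest-energy non-event windows (hard negatives —
that is where impulsive interference lives) plus random ones. One subtlety
matters a great deal: by the onset-containment labeling rule, the window
starting just *after* an event onset contains almost the whole event yet is
labeled negative. Such event-overlapping windows are excluded from the
negative candidate pool — sampling them (and a hard-negative picker would,
preferentially, since they are energetic) injects systematic label noise
that demonstrably stalls training. The labels themselves are untouched;
only which negatives are *sampled* changes.

The pool also includes a small fraction (about 10%) of *background-only*
clips — noise and impulsive interference with no jump at all, contributing
pure negatives. This matters because the Mel front-end references decibels
to each clip's own maximum: a clip containing no event re-references its
background up to 0 dB and looks systematically different from the quiet
stretches of a jump recording. Without such clips both detectors fire
confidently on jump-free audio; with them, the no-jump case is in the
training distribution.

Cross-validation (`kfold_cv()`) partitions *recordings*, not segments, and
keeps noise-augmented twins in the same fold as their base recording;
anything else would leak nearly identical segments across folds and inflate
the scores.

## Sequential inference and onset localization

`detect_jump()` scans 12-frame segments every 4 frames (33 ms — small
enough that every 50–80 ms event is fully contained in at least one
evaluated segment), groups supra-threshold landing segments into clusters,
and walks the clusters in temporal order, taking each cluster's
maximum-confidence segment as a landing candidate; a candidate whose
energy profile fails the onset-quality gate (below) is skipped and the
scan continues — this is what "exploring the signal until detection"
means operationally. The take-off
is then sought only among segments lying within
$[t_{land} - 0.7\,\mathrm{s},\ t_{land} - 0.15\,\mathrm{s}]$: 0.7 s is the
ceiling of human CMJ flight times, and 0.15 s excludes impossibly short
flights and the landing's own energy. The pipeline's operating threshold on
the sigmoid outputs is deliberately conservative (0.9 by default): on
detectable events the trained detectors saturate near 1, while noise-driven
activations rarely exceed ~0.7, and a false landing trigger is the
costliest error of the whole system — the same precision-first reasoning
that selects precision as the early-stopping monitor. Threshold and stride
are configuration values; the individual scan functions default to the
neutral 0.5.

A detected segment locates an event only to $\pm 50$ ms, so each event is
refined by adaptive energy thresholding: short-time energy in 1 ms bins
over the segment plus 50 ms of context (smoothed with a trailing 5 ms
average, which bridges the beat nulls of low-frequency floor resonances
without ever moving energy earlier in time), normalized to $[0,1]$ by the window
maximum (making the step invariant to global gain), and a threshold
starting at 0.99 that decays by $\times 0.9$ adaptively: first until the
earliest supra-threshold bin is preceded by at least 10 ms of sub-threshold
bins (a genuine quiet gap before the onset), then further for as long as
that gap persists, tracking the event's energy rise down toward the local
noise floor (hard floor 0.05). The onset is the start of the final
supra-threshold run containing the energy peak. The decay factor, floor, silence requirement, and bin length
are exposed in `onset_config()`; the defaults were fixed at design time and
the synthetic generator's ground-truth convention (first sample above 1% of
the event peak) is what they are tested against. Onset resolution is
therefore the 1 ms bin length, and flight-time errors partially cancel
because both onsets are biased the same way by the same procedure.

The landing impact dominates the full-band energy of its neighborhood, so
it is localized on the raw waveform. The take-off cannot be: its 2–12 kHz
transient is roughly 12 dB below the landing, which puts its full-band
energy *below* the low-frequency-heavy background even when the Mel-domain
detector sees it perfectly well (measured full-band onset errors were tens
of milliseconds at +20 dB SNR). `detect_jump()` therefore times the
take-off inside its own 2–12 kHz band, where gym background carries little
power; `localize_onset(band=)` exposes the mechanism and defaults to
full-band.

Localization also reports a quality figure — the peak-to-median bin-energy
ratio of the analysis window — and `detect_jump()` abstains
(`onset_quality_min`, default 10) when an event is too buried to time:
an event the detector can *see* in the Mel domain is not necessarily one
the time domain can *time*, and an unreliable timestamp is worse than an
honest miss.

Failures are explicit: a recording with no supra-threshold landing segment
returns status `no_landing`; a landing without a take-off in its window
returns `no_takeoff`; numeric fields are `NA` unless the status is `ok`.

## What the synthetic generator emulates

The study conditions this package is validated under are synthetic,
generated by `synth_config()`/`make_dataset()`:

* **Take-off**: a 50–80 ms band-limited (2–12 kHz) noise burst with ~1 ms
  attack and exponential decay — the spectrally bright tape-peel transient.
* **Landing**: a 50–80 ms sum of damped 80–400 Hz floor resonances plus a
  short broadband click at impact; its RMS is 4× the take-off's (about
  12 dB), so the landing is the reliable trigger.
* **Background**: pink noise plus slowly amplitude-modulated narrowband
  hums (80–600 Hz), convolved with an exponentially decaying noise kernel
  (reverberation); at least 60% of its power lies below 1 kHz.
* **Impulsive interference**: Poisson-placed (0.5/s default) ball-bounce
  trains (restitution factor 0.6–0.8, geometrically shrinking intervals and
  amplitudes) and single broadband weight drops, with peaks 10–20 dB above
  the background RMS — i.e., of the same order as the landing itself.
* **Mixing**: gym dBA levels cannot map to digital amplitude without
  calibration, so noisiness is an SNR — the clean landing peak over the
  combined noise RMS — swept over $\{+20, +10, +5, 0, -5\}$ dB from quiet
  to severely noisy.
* **Geometry**: recordings of 3–6 s with the jump around the middle third;
  flight times uniform on $[0.30, 0.70]$ s (about 11–60 cm jumps), rounded
  to the sample grid so annotations are exact; one jump per recording.
* **Augmentation**: each base recording can be duplicated with freshly
  drawn noise over the identical clean track and annotation, doubling the
  set the way noise-addition augmentation doubles a real recording corpus.

Everything is seeded and bitwise reproducible. What the generator does
*not* emulate: real room acoustics (image-source reverberation, early
reflections), microphone nonlinearity and compression, athlete-specific
footwear/floor variability, or non-jump body sounds. Passing tests on this
data therefore demonstrate that the architecture, training protocol, and
sequential inference work as designed under controlled, realistic-shaped
noise — not that the trained weights transfer to any particular gym.

## Numerical choices and degenerate inputs

* WAV I/O is PCM16 (plus float32 read); the write/read round trip is exact
  to the $2^{-15}$ quantization step, which the tests assert.
* An all-silent analysis window is a degenerate input for onset
  localization (normalization would divide by zero) and errors explicitly;
  likewise clips shorter than one 800-sample window, segment requests on
  stacks with fewer than 12 frames, and mixing against a zero-RMS noise
  track.
* Batch normalization uses $\epsilon = 10^{-5}$ and momentum 0.9 for
  running statistics; minibatches of fewer than 2 samples are skipped.
* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss.
* The false-positive window is *closed*: a landing exactly 50 ms from the
  truth is correct. The convention is fixed here because ties, while
  measure-zero in theory, do occur on the 1 ms onset grid.
* Error statistics use the sample (n−1) standard deviation.

## Problem sizes

The reported accuracy run (`scripts/acceptance.R`, and the corresponding
test) trains on 420 synthetic recordings (210 base × noise augmentation)
with 2 hard + 2 random negative segments per recording alongside all
positives plus 40 background-only clips, for 6 epochs with early-stopping
patience 5 — a reduced-epoch version of the 100-epoch reference protocol,
sized so a complete train + evaluate cycle runs on a single CPU in minutes.
Held-out evaluation uses 50 independently seeded recordings across the full
SNR sweep. Unit tests use a
deliberately small detector (4/8/16 filters) on easy high-SNR data; the
full-size architecture is exercised by the gradient checks and the
accuracy run.

## Known limitations

* Detection recall degrades at the noisy end of the sweep (0 and −5 dB):
  a landing whose peak sits below the noise RMS is often an honest
  `no_landing`/`no_takeoff` miss. The design goal is that what *is*
  reported is accurate (no false landings, millisecond-scale flight-time
  error), not that every buried jump is recovered.
* One jump per recording; no streaming or multi-jump segmentation.
* The naive energy baseline (`naive_energy_baseline()`) is intentionally
  simple — largest low-frequency energy peak plus its best preceding peak —
  and serves as the comparison point for robustness claims, not as a
  faithful reimplementation of any particular classical algorithm.
* Training the full-size detector is the slow path (minutes, not seconds);
  the package trades training speed for having zero framework
  dependencies.
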