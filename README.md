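# soundjump

Measure vertical jump height from the sound a jump makes.

A countermovement jump produces two acoustic events: a quiet take-off
transient (a strip of adhesive tape on the shoe sole peeling off at
push-off) and a much louder landing impact. The interval between them — the
flight time *t* — converts to jump height by ballistic kinematics:

    h = g t² / 8,        g = 9.81 m/s²

so a 495 ms flight corresponds to a 30 cm jump, and a 7 ms timing error
moves the height estimate by only `g·t·Δt/4 ≈ 8.5 mm`. The hard part is
timing the two events in a working gym: 70–90 dBA of music, voices,
bouncing balls and dropped weights defeat simple energy thresholds.

`soundjump` detects the events with two binary convolutional neural
networks over 100 ms slices of a 128-band Mel spectrogram stacked with its
delta and delta–delta features (the landing, being louder, acts as the
trigger; the take-off is then sought only in the physiologically possible
0.7 s window before it), refines each detected segment to a millisecond
onset with an adaptive short-time-energy threshold, and reports flight time
and height. The CNN — about 911,000 parameters — is implemented entirely
in-package (Rcpp convolution kernels + base-R layers and Adam), with every
analytic gradient verified against finite differences in the test suite.

Because the recordings behind the original study are not public, the
package ships a first-class synthetic-data generator that emulates the
study conditions: 50–80 ms events with the landing ~12 dB louder, pink +
narrowband reverberant background with ≥60 % of its power below 1 kHz,
Poisson-placed ball bounces and weight drops, and SNR-controlled mixing
over a +20…−5 dB sweep. All generation is seeded and bitwise reproducible.

## Worked example

```r
library(soundjump)

# one noisy synthetic jump with a known 0.495 s flight
cfg <- synth_config(flight_time_range = c(0.495, 0.495), snr_db = 20)
rec <- synth_jump_recording(cfg, seed = 7)
rec
#> <synthetic_recording> rec1: 5.97 s @ 48000 Hz | takeoff 2.7140 s,
#>   landing 3.2090 s (flight 0.495 s) | SNR 20 dB

# train the two detectors on a synthetic corpus (about ten minutes on one CPU)
train <- make_dataset(210, synth_config(seed = 1), augment = TRUE,
                      keep_components = FALSE)
fits <- train_jump_detectors(train,
                             train_config(epochs = 6, early_stop_patience = 5),
                             n_hard = 2L, n_random = 2L, n_background = 40L,
                             synth_cfg = synth_config(seed = 1))

# sequential detection: landing trigger -> take-off search -> onset refinement
det <- detect_jump(rec$clip, fits$landing, fits$takeoff, recording_id = rec$id)
det
#> <jump_detection> rec1: flight 0.496 s -> height 0.301 m
#>   (takeoff 2.713 s, landing 3.209 s; conf 0.94/0.97)
```

The recovered flight of 0.496 s against the annotated 0.495 s is a 1 ms
error — about 1.2 mm of height (`dh = g·t·Δt/4`); `height 0.301 m` is
`9.81 · 0.496² / 8`. Recordings where no landing clears the detector, or
where an event is too buried in noise for reliable onset timing, come back
with status `no_landing`/`no_takeoff` and no fabricated numbers rather than
an unreliable measurement.

A command-line front-end (`inst/cli/soundjump`) exposes the same pipeline
as `synth`, `train`, `detect`, and `eval` subcommands with a YAML
configuration file and JSON run manifests.

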