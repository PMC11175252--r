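# Synthetic jump-audio generator.
#
# Emulates the acoustic structure of a countermovement jump recorded by a
# smartphone in a sports facility: a quiet high-frequency take-off transient
# (adhesive tape peeling off the sole at push-off), a louder landing impact
# exciting low floor resonances, steady low-frequency-weighted reverberant
# background (music/voices/murmur), and impulsive interference (bouncing
# balls, weight drops). Real gym levels of 70-90 dBA cannot be mapped to
# digital amplitude without calibration, so noisiness is controlled by the
# SNR of the landing peak against the noise RMS.

#' Configuration for the synthetic jump generator
#'
#' @param sample_rate sampling rate in Hz.
#' @param flight_time_range flight-time range in seconds; must lie in
#'   (0, 0.7\], the physiological bound for a vertical jump. The default
#'   0.30-0.70 s spans roughly 11-60 cm jumps under `h = g t^2 / 8`.
#' @param takeoff_duration_range,landing_duration_range event duration ranges
#'   in seconds, within \[0.05, 0.08\] (jump transients last 50-80 ms).
#' @param landing_to_takeoff_level_ratio linear RMS ratio (> 1) of landing to
#'   take-off; landings are substantially louder than take-offs. Default 4
#'   (about 12 dB).
#' @param background_kind one of `"none"`, `"steady"`,
#'   `"steady_plus_impulses"`.
#' @param snr_db SNR in dB of the clean landing peak over the noise RMS.
#'   May be a vector, in which case recordings in a dataset cycle through it
#'   (default sweep +20 ... -5 dB, quiet to highly noisy). `Inf` means no
#'   noise.
#' @param impulse_rate mean impulsive-interference events per second.
#' @param duration_range recording length range in seconds; the jump is
#'   placed around the middle third.
#' @param seed integer RNG seed used by [make_dataset()].
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(sample_rate = 48000L,
                         flight_time_range = c(0.30, 0.70),
                         takeoff_duration_range = c(0.05, 0.08),
                         landing_duration_range = c(0.05, 0.08),
                         landing_to_takeoff_level_ratio = 4,
                         background_kind = c("steady_plus_impulses", "steady",
                                             "none"),
                         snr_db = c(20, 10, 5, 0, -5),
                         impulse_rate = 0.5,
                         duration_range = c(3, 6),
                         seed = 1L) {
  background_kind <- match.arg(background_kind)
  cfg <- list(sample_rate = as.integer(sample_rate),
              flight_time_range = as.numeric(flight_time_range),
              takeoff_duration_range = as.numeric(takeoff_duration_range),
              landing_duration_range = as.numeric(landing_duration_range),
              landing_to_takeoff_level_ratio =
                as.numeric(landing_to_takeoff_level_ratio),
              background_kind = background_kind,
              snr_db = as.numeric(snr_db),
              impulse_rate = as.numeric(impulse_rate),
              duration_range = as.numeric(duration_range),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  sample_rate: %d Hz | flight: [%.2f, %.2f] s | L/T ratio: %.1f\n",
              x$sample_rate, x$flight_time_range[1], x$flight_time_range[2],
              x$landing_to_takeoff_level_ratio))
  cat(sprintf("  background: %s | snr_db: %s | impulse_rate: %.2f /s | seed %d\n",
              x$background_kind, paste(x$snr_db, collapse = ","),
              x$impulse_rate, x$seed))
  invisible(x)
}

validate_synth_config <- function(cfg) {
  rng <- cfg$flight_time_range
  if (length(rng) != 2 || rng[1] <= 0 || rng[2] > 0.7 || rng[1] > rng[2])
    stop("flight_time_range must lie within (0, 0.7] s")
  for (nm in c("takeoff_duration_range", "landing_duration_range")) {
    d <- cfg[[nm]]
    if (length(d) != 2 || d[1] < 0.05 || d[2] > 0.08 || d[1] > d[2])
      stop(nm, " must lie within [0.05, 0.08] s")
  }
  if (cfg$landing_to_takeoff_level_ratio <= 1)
    stop("landing_to_takeoff_level_ratio must exceed 1 (landings are louder)")
  if (cfg$impulse_rate < 0) stop("impulse_rate must be >= 0")
  if (length(cfg$duration_range) != 2 || cfg$duration_range[1] <= 0 ||
      cfg$duration_range[1] > cfg$duration_range[2])
    stop("invalid duration_range")
  invisible(TRUE)
}

# Reference digital levels (dimensionless amplitude). Take-off events are
# normalized to RMS .TAKEOFF_RMS; landings to ratio x that; the steady
# background is built at RMS .BG_RMS and rescaled at mix time by the SNR.
.TAKEOFF_RMS <- 0.05
.BG_RMS <- 0.1

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

.rms <- function(x) sqrt(mean(x^2))

# first sample exceeding 1% of the waveform's peak: the generator's onset
# ground-truth convention.
.onset_index <- function(x) which(abs(x) > 0.01 * max(abs(x)))[1]

.lead_silence_s <- 0.005

#' Synthesize a take-off transient
#'
#' A take-off is the brief tape-peel/push-off sound: a band-limited noise
#' burst emphasizing 2-12 kHz with a sub-millisecond attack and exponential
#' decay, preceded by 5 ms of silence. Output RMS over the nominal duration
#' is fixed at the generator's take-off reference level.
#'
#' @param config a [synth_config()].
#' @param seed optional RNG seed for a reproducible event.
#' @return A list: `clip` ([audio_clip()]), `onset` (seconds from clip start
#'   of the first sample exceeding 1% of the event peak), `duration`
#'   (nominal event duration, seconds).
#' @export
synth_takeoff_event <- function(config = synth_config(), seed = NULL) {
  .with_seed(seed, {
    fs <- config$sample_rate
    d <- stats::runif(1, config$takeoff_duration_range[1],
                      config$takeoff_duration_range[2])
    n <- round(d * fs)
    bp <- signal::butter(4, c(2000, 12000) / (fs / 2), type = "pass")
    burst <- signal::filter(bp, stats::rnorm(n + 200))[-seq_len(200)]
    tt <- seq_len(n) / fs
    attack <- pmin(1, tt / 0.001)                  # ~1 ms attack
    env <- attack * exp(-tt / (d / 4.6))           # ~1% of peak at t = d
    x <- as.numeric(burst) * env
    x <- x / .rms(x) * .TAKEOFF_RMS
    lead <- numeric(round(.lead_silence_s * fs))
    x <- c(lead, x)
    list(clip = audio_clip(x, fs), onset = (.onset_index(x) - 1) / fs,
         duration = d)
  })
}

#' Synthesize a landing impact
#'
#' A landing is the feet-on-floor impact: a sum of damped low-frequency floor
#' resonances (80-400 Hz) plus a short broadband click at the impact instant,
#' preceded by 5 ms of silence. Its RMS over the nominal duration equals
#' `landing_to_takeoff_level_ratio` times the take-off reference RMS, making
#' the landing the louder event.
#'
#' @inheritParams synth_takeoff_event
#' @return Same structure as [synth_takeoff_event()].
#' @export
synth_landing_event <- function(config = synth_config(), seed = NULL) {
  .with_seed(seed, {
    fs <- config$sample_rate
    d <- stats::runif(1, config$landing_duration_range[1],
                      config$landing_duration_range[2])
    n <- round(d * fs)
    tt <- seq_len(n) / fs
    k <- sample(3:5, 1)
    freqs <- stats::runif(k, 80, 400)
    amps <- stats::runif(k, 0.5, 1); amps <- amps / sum(amps)
    x <- numeric(n)
    for (j in seq_len(k))
      x <- x + amps[j] * sin(2 * pi * freqs[j] * tt + stats::runif(1, 0, 2 * pi)) *
        exp(-tt / (d / stats::runif(1, 2, 4)))
    click_n <- round(0.004 * fs)
    click <- stats::rnorm(click_n) * exp(-seq_len(click_n) / (0.0015 * fs))
    click <- click / .rms(click) * 0.6 * .rms(x)
    x[seq_len(click_n)] <- x[seq_len(click_n)] + click
    x <- x / .rms(x) * (.TAKEOFF_RMS * config$landing_to_takeoff_level_ratio)
    lead <- numeric(round(.lead_silence_s * fs))
    x <- c(lead, x)
    list(clip = audio_clip(x, fs), onset = (.onset_index(x) - 1) / fs,
         duration = d)
  })
}

#' Synthesize steady gym background noise
#'
#' Steady background of a training facility: pink (1/f) noise plus
#' amplitude-modulated low-frequency narrowband components (music/voices),
#' smeared by an exponentially decaying reverberation kernel. Energy is
#' concentrated in the low frequencies: at least 60% of spectral power falls
#' below 1 kHz. RMS is fixed at the generator's background reference level;
#' the absolute level in a recording is set by the SNR at mix time.
#'
#' @param duration length in seconds.
#' @inheritParams synth_takeoff_event
#' @return An [audio_clip()].
#' @export
synth_background <- function(duration, config = synth_config(), seed = NULL) {
  stopifnot(duration > 0)
  .with_seed(seed, {
    fs <- config$sample_rate
    n <- round(duration * fs)
    pink <- .pink_noise(n, fs)
    # AM narrowband hums at 80-600 Hz with slow (~1-2 Hz) envelopes
    nb <- numeric(n)
    tt <- seq_len(n) / fs
    for (j in 1:3) {
      f0 <- stats::runif(1, 80, 600)
      # moderate AM depth: audible modulation, but the hum stays steady
      am <- 0.8 + 0.2 * sin(2 * pi * stats::runif(1, 0.5, 2) * tt +
                              stats::runif(1, 0, 2 * pi))
      nb <- nb + am * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
    }
    nb <- nb / .rms(nb)
    x <- pink / .rms(pink) + nb
    # reverberation: convolve with an exponentially decaying noise kernel
    kl <- round(0.25 * fs)
    kernel <- stats::rnorm(kl) * exp(-seq_len(kl) / (0.08 * fs))
    x <- .fft_convolve(x, kernel)[seq_len(n)]
    audio_clip(x / .rms(x) * .BG_RMS, fs)
  })
}

# 1/f spectral shaping of white gaussian noise, flat below 20 Hz.
# Synthesized at the next power-of-two length (radix-2 FFT) and truncated.
.pink_noise <- function(n, fs) {
  n2 <- 2^ceiling(log2(n))
  nf <- n2 %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / n2
  shape <- 1 / sqrt(pmax(f, 20))
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * shape
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n2 - nf + 1)])))
  Re(stats::fft(full, inverse = TRUE))[seq_len(n)] / n2
}

.fft_convolve <- function(x, kernel) {
  n <- length(x) + length(kernel) - 1
  nfft <- 2^ceiling(log2(n))
  Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                  stats::fft(c(kernel, numeric(nfft - length(kernel)))),
                inverse = TRUE))[seq_len(n)] / nfft
}

#' Synthesize impulsive interference
#'
#' Poisson-placed interference events of two kinds seen around sports
#' activity: ball bounces (a train of bursts whose intervals and amplitudes
#' shrink geometrically with a restitution factor of 0.6-0.8) and weight
#' drops (a single broadband burst). Peak levels sit 10-20 dB above the
#' steady-background reference RMS, so after SNR scaling they are of the same
#' order as - often louder than - the jump events they must not be confused
#' with.
#'
#' @param duration length in seconds.
#' @inheritParams synth_takeoff_event
#' @return A list: `clip` ([audio_clip()]) and `impulse_times` (numeric
#'   vector of onset seconds, possibly empty).
#' @export
synth_impulses <- function(duration, config = synth_config(), seed = NULL) {
  stopifnot(duration > 0, config$impulse_rate >= 0)
  .with_seed(seed, {
    fs <- config$sample_rate
    n <- round(duration * fs)
    x <- numeric(n)
    m <- stats::rpois(1, config$impulse_rate * duration)
    times <- sort(stats::runif(m, 0, duration))
    for (t0 in times) {
      ev <- if (stats::runif(1) < 0.5) .ball_bounce(fs) else .weight_drop(fs)
      amp <- .BG_RMS * 10^(stats::runif(1, 10, 20) / 20)
      i0 <- round(t0 * fs) + 1L
      i1 <- min(n, i0 + length(ev) - 1L)
      if (i0 <= n)
        x[i0:i1] <- x[i0:i1] + ev[seq_len(i1 - i0 + 1L)] * amp
    }
    list(clip = audio_clip(x, fs), impulse_times = times)
  })
}

# accelerating train of short thuds; restitution shrinks gaps and amplitudes
.ball_bounce <- function(fs) {
  r <- stats::runif(1, 0.6, 0.8)
  k <- sample(4:7, 1)
  gap0 <- stats::runif(1, 0.25, 0.45)
  bp <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
  out <- numeric(round(sum(gap0 * r^(0:(k - 1))) * fs) + round(0.05 * fs))
  pos <- 0
  for (j in seq_len(k)) {
    bl <- round(0.02 * fs)
    b <- as.numeric(signal::filter(bp, stats::rnorm(bl + 100))[-seq_len(100)]) *
      exp(-seq_len(bl) / (0.004 * fs))
    b <- b / max(abs(b)) * r^(j - 1)
    i0 <- round(pos * fs) + 1L
    out[i0:(i0 + bl - 1L)] <- out[i0:(i0 + bl - 1L)] + b
    pos <- pos + gap0 * r^(j - 1)
  }
  out
}

# single broadband burst (barbell/weight hitting the floor)
.weight_drop <- function(fs) {
  bl <- round(stats::runif(1, 0.02, 0.05) * fs)
  b <- stats::rnorm(bl) * exp(-seq_len(bl) / (0.008 * fs))
  b / max(abs(b))
}

#' Mix an event track with a noise track at a prescribed SNR
#'
#' The noise is scaled by `alpha = peak(event) * 10^(-snr_db/20) / rms(noise)`
#' so that `20*log10(event peak / scaled-noise RMS)` equals `snr_db` exactly.
#' `snr_db = Inf` returns the event track unchanged.
#'
#' @param event_track,noise_track [audio_clip()]s of equal length and rate.
#' @param snr_db target SNR in decibels (event peak over scaled-noise RMS).
#' @return The mixed [audio_clip()].
#' @export
mix_at_snr <- function(event_track, noise_track, snr_db) {
  stopifnot(inherits(event_track, "audio_clip"),
            inherits(noise_track, "audio_clip"),
            length(event_track$samples) == length(noise_track$samples),
            event_track$sample_rate == noise_track$sample_rate)
  if (is.infinite(snr_db) && snr_db > 0) return(event_track)
  nr <- .rms(noise_track$samples)
  if (nr == 0)
    stop("noise track has zero RMS; cannot realize a finite SNR")
  alpha <- max(abs(event_track$samples)) * 10^(-snr_db / 20) / nr
  audio_clip(event_track$samples + alpha * noise_track$samples,
             event_track$sample_rate)
}

#' Synthesize one labeled jump recording
#'
#' Builds a 3-6 s recording holding exactly one take-off and one landing,
#' separated by a flight time drawn uniformly from the configured range and
#' rounded to the sample grid; the flight interval is near-silent in the
#' clean track (the athlete is airborne). Background and impulsive
#' interference are added per `config$background_kind`, with the combined
#' noise scaled so the clean landing peak sits `snr_db` dB above the noise
#' RMS. The annotation holds the true event onsets (1%-of-peak convention) on
#' the sample grid.
#'
#' @inheritParams synth_takeoff_event
#' @param id recording identifier.
#' @param snr_db optional SNR override; by default drawn from `config$snr_db`.
#' @return An object of class `synthetic_recording`: `id`, `base_id`, `clip`,
#'   `annotation` (one-row data.frame `recording_id,takeoff_s,landing_s`),
#'   `components` (clean/background/impulses [audio_clip()]s summing to
#'   `clip`), `impulse_times`, `flight_s`, `snr_db`, `config_used`.
#' @export
synth_jump_recording <- function(config = synth_config(), seed = NULL,
                                 id = "rec1", snr_db = NULL) {
  .with_seed(seed, {
    fs <- config$sample_rate
    dur <- stats::runif(1, config$duration_range[1], config$duration_range[2])
    n <- round(dur * fs)
    if (is.null(snr_db))
      snr_db <- if (config$background_kind == "none") Inf
                else if (length(config$snr_db) == 1L) config$snr_db
                else sample(config$snr_db, 1)
    flight <- stats::runif(1, config$flight_time_range[1],
                           config$flight_time_range[2])
    flight_n <- round(flight * fs)
    to <- synth_takeoff_event(config)
    la <- synth_landing_event(config)
    # take-off onset lands in the middle third of the recording
    t_to <- stats::runif(1, dur / 3, dur / 2)
    a <- round(t_to * fs)                      # onset sample index - 1
    clean <- numeric(n)
    clean <- .add_at(clean, to$clip$samples, a - round(to$onset * fs))
    clean <- .add_at(clean, la$clip$samples, a + flight_n - round(la$onset * fs))
    ann <- data.frame(recording_id = id,
                      takeoff_s = a / fs,
                      landing_s = (a + flight_n) / fs,
                      stringsAsFactors = FALSE)
    bg <- numeric(n); imp <- numeric(n); imp_times <- numeric(0)
    if (config$background_kind != "none") {
      bg <- synth_background(dur, config)$samples[seq_len(n)]
      if (config$background_kind == "steady_plus_impulses") {
        si <- synth_impulses(dur, config)
        imp <- si$clip$samples[seq_len(n)]
        imp_times <- si$impulse_times
      }
      noise <- bg + imp
      alpha <- max(abs(clean)) * 10^(-snr_db / 20) / .rms(noise)
      bg <- alpha * bg
      imp <- alpha * imp
    }
    # keep the mix inside full scale so PCM16 emission never clips; a
    # global gain leaves every SNR and level ratio untouched
    peak <- max(abs(clean + bg + imp))
    if (peak > 0.99) {
      s <- 0.99 / peak
      clean <- clean * s; bg <- bg * s; imp <- imp * s
    }
    structure(list(id = id, base_id = id,
                   clip = audio_clip(clean + bg + imp, fs),
                   annotation = ann,
                   components = list(clean = audio_clip(clean, fs),
                                     background = audio_clip(bg, fs),
                                     impulses = audio_clip(imp, fs)),
                   impulse_times = imp_times,
                   flight_s = flight_n / fs,
                   snr_db = snr_db,
                   config_used = config),
              class = "synthetic_recording")
  })
}

.add_at <- function(x, ev, at0) {     # at0: 0-based start offset
  i0 <- at0 + 1L
  i1 <- min(length(x), i0 + length(ev) - 1L)
  if (i0 >= 1L && i0 <= length(x))
    x[i0:i1] <- x[i0:i1] + ev[seq_len(i1 - i0 + 1L)]
  x
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s: %.2f s @ %d Hz | takeoff %.4f s, landing %.4f s (flight %.3f s) | SNR %s dB\n",
              x$id, clip_duration(x$clip), x$clip$sample_rate,
              x$annotation$takeoff_s, x$annotation$landing_s, x$flight_s,
              format(x$snr_db)))
  invisible(x)
}

#' Splice a take-off and a landing event into a synthetic jump
#'
#' Concatenates a take-off and a landing event so that the landing onset sits
#' exactly `round(gap * fs)` samples after the take-off onset - the
#' sample-aligned construction used to probe flight-time recovery at
#' arbitrary imposed gaps.
#'
#' @param takeoff,landing event lists as returned by
#'   [synth_takeoff_event()] / [synth_landing_event()] (`clip` + `onset`).
#' @param gap imposed flight time in seconds, in (0, 0.7\].
#' @param lead,tail silence (seconds) before the take-off onset and after the
#'   landing event.
#' @param id recording identifier.
#' @return A `synthetic_recording` with a clean (noise-free) clip whose
#'   annotated flight time equals `round(gap*fs)/fs` exactly.
#' @export
splice_synthetic_jump <- function(takeoff, landing, gap, lead = 1, tail = 1,
                                  id = "splice1") {
  if (gap <= 0 || gap > 0.7)
    stop("gap must lie in (0, 0.7] s (physiological flight-time bound)")
  fs <- takeoff$clip$sample_rate
  stopifnot(fs == landing$clip$sample_rate)
  gap_n <- round(gap * fs)
  a <- round(lead * fs)
  n <- a + gap_n + length(landing$clip$samples) + round(tail * fs)
  clean <- numeric(n)
  clean <- .add_at(clean, takeoff$clip$samples, a - round(takeoff$onset * fs))
  clean <- .add_at(clean, landing$clip$samples, a + gap_n - round(landing$onset * fs))
  ann <- data.frame(recording_id = id, takeoff_s = a / fs,
                    landing_s = (a + gap_n) / fs, stringsAsFactors = FALSE)
  structure(list(id = id, base_id = id,
                 clip = audio_clip(clean, fs),
                 annotation = ann,
                 components = list(clean = audio_clip(clean, fs),
                                   background = audio_clip(numeric(n), fs),
                                   impulses = audio_clip(numeric(n), fs)),
                 impulse_times = numeric(0),
                 flight_s = gap_n / fs,
                 snr_db = Inf,
                 config_used = NULL),
            class = "synthetic_recording")
}

#' Generate a labeled synthetic dataset
#'
#' Generates `n` base recordings under `config` (seeded by `config$seed`,
#' hence bitwise-reproducible). With `augment = TRUE` each base recording is
#' duplicated with freshly randomized noise over the same clean events and
#' annotation - the noise-addition augmentation that doubles a dataset
#' (300 base jumps become 600 training samples).
#'
#' @param n number of base recordings (> 0).
#' @param config a [synth_config()].
#' @param augment duplicate each base recording with fresh noise?
#' @param id_prefix prefix for recording identifiers.
#' @param keep_components retain the per-recording component tracks
#'   (clean/background/impulses). They triple the memory of a dataset;
#'   disable for large training sets.
#' @return A list of `synthetic_recording`s (length `n`, or `2n` when
#'   augmented; augmented twins carry id `<base>_aug` and the same `base_id`).
#' @export
make_dataset <- function(n, config = synth_config(), augment = FALSE,
                         id_prefix = "rec", keep_components = TRUE) {
  stopifnot(n > 0)
  set.seed(config$seed)
  out <- vector("list", if (augment) 2L * n else n)
  j <- 0L
  for (i in seq_len(n)) {
    id <- sprintf("%s%04d", id_prefix, i)
    snr <- if (config$background_kind == "none") Inf
           else config$snr_db[(i - 1L) %% length(config$snr_db) + 1L]
    rec <- synth_jump_recording(config, id = id, snr_db = snr)
    twin <- if (augment) .augment_recording(rec, config)
    if (!keep_components) {
      rec$components <- NULL
      if (!is.null(twin)) twin$components <- NULL
    }
    out[[j <- j + 1L]] <- rec
    if (augment) out[[j <- j + 1L]] <- twin
  }
  out
}

# fresh background + impulses over the same clean track and annotation
.augment_recording <- function(rec, config) {
  fs <- config$sample_rate
  clean <- rec$components$clean$samples
  n <- length(clean)
  dur <- n / fs
  bg <- numeric(n); imp <- numeric(n); imp_times <- numeric(0)
  snr <- rec$snr_db
  if (config$background_kind != "none") {
    bg <- synth_background(dur, config)$samples[seq_len(n)]
    if (config$background_kind == "steady_plus_impulses") {
      si <- synth_impulses(dur, config)
      imp <- si$clip$samples[seq_len(n)]
      imp_times <- si$impulse_times
    }
    noise <- bg + imp
    alpha <- max(abs(clean)) * 10^(-snr / 20) / .rms(noise)
    bg <- alpha * bg
    imp <- alpha * imp
  }
  peak <- max(abs(clean + bg + imp))
  if (peak > 0.99) {
    s <- 0.99 / peak
    clean <- clean * s; bg <- bg * s; imp <- imp * s
  }
  ann <- rec$annotation
  ann$recording_id <- paste0(rec$id, "_aug")
  structure(list(id = paste0(rec$id, "_aug"), base_id = rec$base_id,
                 clip = audio_clip(clean + bg + imp, fs),
                 annotation = ann,
                 components = list(clean = audio_clip(clean, fs),
                                   background = audio_clip(bg, fs),
                                   impulses = audio_clip(imp, fs)),
                 impulse_times = imp_times,
                 flight_s = rec$flight_s,
                 snr_db = snr,
                 config_used = config),
            class = "synthetic_recording")
}

#' Write a synthetic dataset to disk
#'
#' One PCM16 WAV per recording, one annotation CSV
#' (`recording_id,takeoff_s,landing_s`), and a JSON manifest recording the
#' generator configuration, seed, and per-recording SNR/flight time.
#'
#' @param recordings list of `synthetic_recording`s.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(recordings, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anns <- do.call(rbind, lapply(recordings, `[[`, "annotation"))
  for (rec in recordings)
    write_wav(rec$clip, file.path(out_dir, paste0(rec$id, ".wav")))
  write_annotations(anns, file.path(out_dir, "annotations.csv"))
  cfg <- recordings[[1]]$config_used
  snrs <- vapply(recordings, `[[`, 0, "snr_db")
  snrs[is.infinite(snrs)] <- NA
  manifest <- list(
    n_recordings = length(recordings),
    config = lapply(unclass(cfg), function(x) x),
    recordings = data.frame(
      recording_id = vapply(recordings, `[[`, "", "id"),
      base_id = vapply(recordings, `[[`, "", "base_id"),
      snr_db = snrs,
      flight_s = vapply(recordings, `[[`, 0, "flight_s")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
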