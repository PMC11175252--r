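# Sequential inference: the louder landing is the trigger; the take-off is
# then sought only in the physiologically possible window (at most 0.7 s)
# before it. Detected segments are refined to exact event onsets with an
# adaptive short-time-energy threshold, and flight time converts to jump
# height by ballistic kinematics.

.GRAVITY <- 9.81
.SEG_SPAN_S <- 0.1

#' Configuration of the adaptive-threshold onset localizer
#'
#' @param energy_frame short-time-energy bin length in seconds (the onset
#'   resolution; default 1 ms).
#' @param initial_threshold starting threshold on \[0, 1\]-normalized energy,
#'   near 1.
#' @param threshold_decay multiplicative decay applied when the threshold
#'   must adapt downwards (0 < decay < 1).
#' @param floor_threshold lowest admissible threshold.
#' @param context_pad seconds of context analyzed on each side of a detected
#'   segment.
#' @param min_silence quiet time (seconds) required before an accepted onset.
#' @return An object of class `onset_config`.
#' @export
onset_config <- function(energy_frame = 0.001, initial_threshold = 0.99,
                         threshold_decay = 0.9, floor_threshold = 0.05,
                         context_pad = 0.05, min_silence = 0.010) {
  stopifnot(energy_frame > 0, floor_threshold > 0,
            floor_threshold < initial_threshold, initial_threshold <= 1,
            threshold_decay > 0, threshold_decay < 1)
  structure(list(energy_frame = energy_frame,
                 initial_threshold = initial_threshold,
                 threshold_decay = threshold_decay,
                 floor_threshold = floor_threshold,
                 context_pad = context_pad,
                 min_silence = min_silence),
            class = "onset_config")
}

#' Scan a feature stack for the landing event
#'
#' Evaluates sliding 12-frame segments every `stride_frames` frames with the
#' trained landing detector, groups consecutive supra-threshold segments into
#' clusters, and returns the maximum-confidence segment of the *first*
#' cluster — the landing acts as the trigger of the whole pipeline. Returns
#' `NULL` when nothing exceeds the threshold (no jump in the recording).
#'
#' @param stack a `feature_stack` of the full recording.
#' @param model a trained landing `jump_cnn`.
#' @param stride_frames scan stride in frames (default 4, about 33 ms, so
#'   every 50-80 ms event is fully inside at least one evaluated segment).
#' @param threshold detection probability threshold.
#' @param all_clusters return every cluster (in temporal order) instead of
#'   only the first; [detect_jump()] walks them sequentially so that a
#'   cluster rejected by the onset-quality gate does not end the scan.
#' @return `NULL`, or a list with `time` (segment center, seconds),
#'   `segment_start`, and `confidence` (with `all_clusters = TRUE`, an
#'   unnamed list of such lists).
#' @export
scan_for_landing <- function(stack, model, stride_frames = 4L,
                             threshold = 0.5, all_clusters = FALSE) {
  stopifnot(inherits(stack, "feature_stack"), inherits(model, "jump_cnn"))
  if (!model$trained) stop("landing model is untrained")
  sb <- segment_stack(stack, stride_frames)
  prob <- predict(model, sb)
  sup <- which(prob >= threshold)
  if (!length(sup)) return(NULL)
  cl <- cumsum(c(1, diff(sup) > 1))
  clusters <- lapply(unname(split(sup, cl)), function(ix) {
    best <- ix[which.max(prob[ix])]
    list(time = sb$segment_start_times[best] + .SEG_SPAN_S / 2,
         segment_start = sb$segment_start_times[best],
         confidence = prob[best])
  })
  if (all_clusters) clusters else clusters[[1]]
}

#' Search for the take-off preceding a detected landing
#'
#' Evaluates only segments whose span lies within
#' `[landing_time - max_lookback, landing_time - min_flight]` and returns
#' the maximum-confidence supra-threshold one. The 0.7 s lookback is the
#' physiological ceiling on flight time; `min_flight` excludes impossibly
#' short flights and the landing's own energy.
#'
#' @param stack a `feature_stack` of the full recording.
#' @param model a trained take-off `jump_cnn`.
#' @param landing_time landing instant in seconds (from
#'   [scan_for_landing()] or the localized onset).
#' @param max_lookback,min_flight search window bounds in seconds.
#' @param stride_frames scan stride in frames.
#' @param threshold detection probability threshold.
#' @return `NULL`, or a list as in [scan_for_landing()].
#' @export
search_for_takeoff <- function(stack, model, landing_time,
                               max_lookback = 0.7, min_flight = 0.15,
                               stride_frames = 4L, threshold = 0.5) {
  stopifnot(inherits(stack, "feature_stack"), inherits(model, "jump_cnn"))
  if (!model$trained) stop("take-off model is untrained")
  if (landing_time < min_flight)
    stop("landing at ", landing_time, " s leaves no room for a take-off ",
         "(min_flight = ", min_flight, " s)")
  sb <- segment_stack(stack, stride_frames)
  st <- sb$segment_start_times
  ok <- st >= landing_time - max_lookback &
    st + .SEG_SPAN_S <= landing_time - min_flight
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  prob <- numeric(length(st))
  prob[idx] <- predict(model, .subset_batch(sb, ok))
  cand <- idx[prob[idx] >= threshold]
  if (!length(cand)) return(NULL)
  best <- cand[which.max(prob[cand])]
  list(time = st[best] + .SEG_SPAN_S / 2,
       segment_start = st[best],
       confidence = prob[best])
}

#' Localize an event onset by adaptive energy thresholding
#'
#' Within a window of one segment span plus `context_pad` on each side of
#' `window_center`: (1) short-time energy in `energy_frame` bins; (2)
#' normalization to \[0, 1\] by the window maximum — making the result
#' invariant to global gain; (3) a threshold starting near 1 selects
#' supra-threshold bins; (4) while the earliest supra-threshold bin is not
#' preceded by at least `min_silence` of sub-threshold bins (and the
#' threshold is above its floor), the threshold decays multiplicatively,
#' adapting downwards to the signal's energy fluctuations; (5) the onset is
#' the start time of the earliest bin of the final supra-threshold run that
#' contains the energy peak.
#'
#' @param clip the full [audio_clip()].
#' @param window_center center of the detected segment in seconds.
#' @param config an [onset_config()].
#' @param band optional `c(low, high)` band in Hz: the window is band-pass
#'   filtered before the energy analysis. Quiet events whose energy lives
#'   in a band where the background is weak (the 2-12 kHz take-off
#'   transient under low-frequency gym noise) are only localizable in
#'   their own band; `NULL` analyzes the raw full-band waveform.
#' @return Onset in seconds from clip start, at `energy_frame` resolution,
#'   with attribute `prominence` (peak-to-median bin-energy ratio of the
#'   analysis window).
#' @export
localize_onset <- function(clip, window_center, config = onset_config(),
                           band = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  half <- .SEG_SPAN_S / 2 + config$context_pad
  i0 <- max(1L, round((window_center - half) * fs) + 1L)
  i1 <- min(length(clip$samples), round((window_center + half) * fs))
  if (i1 <= i0) stop("onset window lies outside the clip")
  x <- clip$samples[i0:i1]
  if (!is.null(band)) {
    bf <- if (band[2] >= fs / 2)
      signal::butter(4, band[1] / (fs / 2), type = "high")
    else signal::butter(4, band / (fs / 2), type = "pass")
    x <- as.numeric(signal::filter(bf, x))
  }
  bin <- max(1L, round(config$energy_frame * fs))
  nb <- length(x) %/% bin
  if (nb < 2L || all(x == 0)) stop("degenerate (silent) onset window")
  e_raw <- colSums(matrix(x[seq_len(nb * bin)]^2, nrow = bin))
  # trailing 5-bin average: bridges the beat nulls of low-frequency
  # resonances without ever moving energy earlier in time
  e <- e_raw
  if (nb >= 5L) {
    cs <- cumsum(e_raw)
    e <- (cs - c(rep(0, 5L), cs[seq_len(nb - 5L)])) / 5
    e[1:4] <- cs[1:4] / (1:4)
  }
  e <- e / max(e)
  nsil <- max(1L, ceiling(config$min_silence / config$energy_frame))
  quiet_gap <- function(th) {
    first <- which(e >= th)[1]
    first > nsil && all(e[(first - nsil):(first - 1)] < th)
  }
  theta <- config$initial_threshold
  # decay until a quiet gap precedes the earliest supra-threshold bin ...
  while (!quiet_gap(theta) && theta > config$floor_threshold)
    theta <- max(theta * config$threshold_decay, config$floor_threshold)
  # ... then keep adapting downwards while the gap persists, tracking the
  # event's energy rise as far down as the local noise floor allows
  repeat {
    cand <- theta * config$threshold_decay
    if (cand < config$floor_threshold || !quiet_gap(cand)) break
    theta <- cand
  }
  sup <- e >= theta
  runs <- rle(sup)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak <- which.max(e)
  r <- which(runs$values & starts <= peak & ends >= peak)
  onset_bin <- starts[r[1]]
  onset <- (i0 - 1L + (onset_bin - 1L) * bin) / fs
  # peak-to-median ratio of the raw (unsmoothed) bin energies: how much the
  # event stands out of its local noise floor (callers may gate on it)
  attr(onset, "prominence") <- max(e_raw) /
    max(stats::median(e_raw), .Machine$double.eps)
  onset
}

#' Flight time and jump height from event onsets
#'
#' `t = landing - takeoff`; under uniform gravity the center of mass rises
#' `h = g t^2 / 8` (g = 9.81 m/s^2). The first-order height sensitivity to a
#' timing error is `dh = g t dt / 4` (see [height_sensitivity()]): 7 ms at a
#' 495 ms flight moves the height by about 8.5 mm.
#'
#' @param takeoff_onset,landing_onset onsets in seconds; the flight time must
#'   lie in (0, 0.7\].
#' @return A list with `flight_s` and `height_m`.
#' @export
flight_time_and_height <- function(takeoff_onset, landing_onset) {
  t <- landing_onset - takeoff_onset
  if (t <= 0) stop("flight time ", round(t, 4), " s is not positive")
  if (t > 0.7) stop("flight time ", round(t, 4),
                    " s exceeds the 0.7 s physiological bound")
  list(flight_s = t, height_m = jump_height(t))
}

#' Ballistic jump kinematics
#'
#' `jump_height(t) = g t^2 / 8` converts flight time to the rise of the
#' center of mass; `flight_from_height()` is its closed-form inverse
#' `t = sqrt(8 h / g)`; `height_sensitivity()` is the first-order error
#' propagation `dh = g t dt / 4`.
#'
#' @param t flight time in seconds.
#' @param h jump height in meters.
#' @param dt flight-time error in seconds.
#' @param g gravitational acceleration, m/s^2.
#' @return Height in meters, flight time in seconds, or height error in
#'   meters respectively.
#' @export
jump_height <- function(t, g = .GRAVITY) g * t^2 / 8

#' @rdname jump_height
#' @export
flight_from_height <- function(h, g = .GRAVITY) sqrt(8 * h / g)

#' @rdname jump_height
#' @export
height_sensitivity <- function(t, dt, g = .GRAVITY) g * t * dt / 4

#' Detect a jump in a recording and measure its height
#'
#' The full sequential pipeline: Mel/delta/delta-delta features, landing
#' scan (the trigger), take-off search in the preceding window, adaptive
#' onset localization of both events, and flight-time/height computation.
#' On failure of any stage the status records which (`no_landing`,
#' `no_takeoff`) and no numeric measurements are fabricated.
#'
#' @param clip an [audio_clip()] at 48 kHz.
#' @param landing_model,takeoff_model trained `jump_cnn`s.
#' @param stride_frames inference scan stride in frames.
#' @param threshold detection probability threshold of the pipeline. The
#'   default 0.9 is deliberately conservative: detectable events saturate
#'   the sigmoid near 1 while noise-driven activations rarely exceed ~0.7,
#'   and a false landing trigger is the costliest error of the whole
#'   system.
#' @param onset_cfg an [onset_config()].
#' @param max_lookback,min_flight take-off search window in seconds.
#' @param onset_quality_min minimum peak-to-median short-time-energy ratio
#'   an event must exhibit in its localization window to be considered
#'   timeable. Events buried too deep in noise for raw-energy onset
#'   localization are reported as honest misses (`no_landing`/`no_takeoff`)
#'   instead of being assigned unreliable timestamps.
#' @param landing_band,takeoff_band localization bands in Hz passed to
#'   [localize_onset()]. The landing impact dominates the full-band energy
#'   and is localized unfiltered; the much quieter take-off is timed inside
#'   its own 2-12 kHz band, where gym background carries little energy.
#' @param recording_id identifier carried into the result.
#' @return An object of class `jump_detection` with `recording_id`,
#'   `status` (`ok`/`no_landing`/`no_takeoff`), `takeoff_onset`,
#'   `landing_onset`, `flight_s`, `height_m`, `landing_confidence`,
#'   `takeoff_confidence` (numeric fields are `NA` unless `status == "ok"`,
#'   except the landing fields which are set once a landing is found).
#' @export
detect_jump <- function(clip, landing_model, takeoff_model,
                        stride_frames = 4L, threshold = 0.9,
                        onset_cfg = onset_config(),
                        max_lookback = 0.7, min_flight = 0.15,
                        onset_quality_min = 10,
                        landing_band = NULL, takeoff_band = c(2000, 12000),
                        recording_id = "rec") {
  res <- list(recording_id = recording_id, status = "no_landing",
              takeoff_onset = NA_real_, landing_onset = NA_real_,
              flight_s = NA_real_, height_m = NA_real_,
              landing_confidence = NA_real_, takeoff_confidence = NA_real_)
  class(res) <- "jump_detection"
  stack <- feature_stack(clip)
  cands <- scan_for_landing(stack, landing_model, stride_frames, threshold,
                            all_clusters = TRUE)
  if (is.null(cands)) return(res)
  # walk the clusters in temporal order; a cluster whose energy profile is
  # too buried to time is skipped, not fatal — the scan continues
  land <- NULL
  landing_onset <- NULL
  for (cand in cands) {
    on <- tryCatch(localize_onset(clip, cand$time, onset_cfg, landing_band),
                   error = function(e) NULL)
    if (!is.null(on) && attr(on, "prominence") >= onset_quality_min) {
      land <- cand
      landing_onset <- on
      break
    }
  }
  if (is.null(land)) return(res)
  res$landing_onset <- as.numeric(landing_onset)
  res$landing_confidence <- land$confidence
  res$status <- "no_takeoff"
  if (res$landing_onset < min_flight) return(res)
  landing_onset <- res$landing_onset
  toff <- search_for_takeoff(stack, takeoff_model, landing_onset,
                             max_lookback, min_flight, stride_frames,
                             threshold)
  if (is.null(toff)) return(res)
  takeoff_onset <- localize_onset(clip, toff$time, onset_cfg, takeoff_band)
  if (attr(takeoff_onset, "prominence") < onset_quality_min) return(res)
  takeoff_onset <- as.numeric(takeoff_onset)
  ft <- tryCatch(flight_time_and_height(takeoff_onset, landing_onset),
                 error = function(e) NULL)
  if (is.null(ft)) return(res)
  res$takeoff_onset <- takeoff_onset
  res$takeoff_confidence <- toff$confidence
  res$flight_s <- ft$flight_s
  res$height_m <- ft$height_m
  res$status <- "ok"
  res
}

#' @export
print.jump_detection <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<jump_detection> %s: flight %.3f s -> height %.3f m (takeoff %.3f s, landing %.3f s; conf %.2f/%.2f)\n",
                x$recording_id, x$flight_s, x$height_m, x$takeoff_onset,
                x$landing_onset, x$takeoff_confidence, x$landing_confidence))
  else
    cat(sprintf("<jump_detection> %s: %s\n", x$recording_id, x$status))
  invisible(x)
}
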