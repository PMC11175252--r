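# Mel / delta / delta-delta front-end.
#
# The detector input is a 128-band log-Mel spectrogram (800-sample Hann
# window, 50% overlap = 400-sample hop at 48 kHz) stacked with its delta and
# delta-delta features in a third, RGB-like channel dimension, then cut into
# 12-frame (100 ms of hops) segments.

.FRAME_WIN <- 800L
.FRAME_HOP <- 400L
.N_MELS <- 128L
.SEG_FRAMES <- 12L
.DB_FLOOR <- -80

#' Mel filterbank matrix
#'
#' Triangular filters with centers equally spaced on the Mel scale
#' (`2595 log10(1 + f/700)`) between `fmin` and `fmax`, over the non-negative
#' FFT bins of an `n_fft`-point transform.
#'
#' @param n_mels number of bands.
#' @param n_fft FFT length in samples.
#' @param sample_rate sampling rate in Hz.
#' @param fmin,fmax filterbank frequency range in Hz.
#' @return A `n_mels x (n_fft/2 + 1)` matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels = 128L, n_fft = 800L, sample_rate = 48000L,
                           fmin = 20, fmax = sample_rate / 2) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2L + 1L
  fft_f <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (fft_f - lo) / (mid - lo)
    down <- (hi - fft_f) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel spectrogram of an audio clip
#'
#' Hann-windowed power spectra over 800-sample windows hopped by 400 samples
#' (16.7 ms windows, 50% overlap at 48 kHz), mapped through a 128-band Mel
#' filterbank spanning 20 Hz to Nyquist, and converted to decibels referenced
#' to the clip's maximum band power with a -80 dB floor. An all-silent clip
#' therefore sits entirely at the floor. The frame count is
#' `floor((N - 800)/400) + 1`.
#'
#' @param clip an [audio_clip()] at 48 kHz with at least 800 samples.
#' @param n_mels number of Mel bands.
#' @return A `n_mels x T` matrix with attributes `frame_times` (window-center
#'   seconds) and `frame_params`.
#' @export
mel_spectrogram <- function(clip, n_mels = .N_MELS) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate != 48000L)
    stop("mel_spectrogram expects the canonical 48 kHz rate; see resample_to_48k()")
  x <- clip$samples
  win <- .FRAME_WIN; hop <- .FRAME_HOP
  if (length(x) < win)
    stop("clip shorter than one analysis window (", win, " samples)")
  n_frames <- (length(x) - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  frames <- matrix(x[outer(seq_len(win), starts, `+`)], nrow = win) * hann
  spec <- stats::mvfft(frames)[seq_len(win %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(n_mels, win, clip$sample_rate)
  melpow <- fb %*% power
  ref <- max(melpow)
  db <- if (ref > 0) 10 * log10(pmax(melpow / ref, 10^(.DB_FLOOR / 10)))
        else matrix(.DB_FLOOR, nrow(melpow), ncol(melpow))
  structure(db,
            frame_times = (starts + win / 2) / clip$sample_rate,
            frame_params = list(window = win, hop = hop,
                                sample_rate = clip$sample_rate,
                                n_mels = n_mels))
}

#' Delta features by local linear-regression slope
#'
#' Per-band slope of a least-squares line fitted over a +/- `half_width`
#' frame neighborhood (the standard regression-delta formula
#' `sum_d d * x[t+d] / sum_d d^2`); edge frames use replicated padding.
#' Applying it twice yields delta-delta (curvature) features.
#'
#' @param spec a bands x frames matrix.
#' @param half_width neighborhood half width in frames (>= 1).
#' @return A matrix of the same shape.
#' @export
delta_features <- function(spec, half_width = 2L) {
  stopifnot(is.matrix(spec), half_width >= 1L)
  ncol_s <- ncol(spec)
  if (ncol_s < 2L * half_width + 1L)
    stop("need at least ", 2L * half_width + 1L, " frames for half_width ",
         half_width)
  idx <- function(k) pmin(pmax(seq_len(ncol_s) + k, 1L), ncol_s)
  num <- matrix(0, nrow(spec), ncol_s)
  for (d in seq_len(half_width))
    num <- num + d * (spec[, idx(d), drop = FALSE] -
                        spec[, idx(-d), drop = FALSE])
  num / (2 * sum(seq_len(half_width)^2))
}

#' Stack Mel, delta, and delta-delta channels into a feature stack
#'
#' @param mel,delta,delta2 bands x frames matrices of identical shape
#'   (channel 0/1/2 of the stack).
#' @param frame_times frame-center times in seconds (taken from `mel`'s
#'   attribute when omitted).
#' @param frame_params frame geometry list (window, hop, sample_rate).
#' @return An object of class `feature_stack`: `values` (bands x frames x 3
#'   array), `frame_times`, `frame_params`.
#' @export
stack_channels <- function(mel, delta, delta2, frame_times = NULL,
                           frame_params = NULL) {
  if (!all(dim(mel) == dim(delta)) || !all(dim(mel) == dim(delta2)))
    stop("channel shapes differ")
  if (is.null(frame_times)) frame_times <- attr(mel, "frame_times")
  if (is.null(frame_params)) frame_params <- attr(mel, "frame_params")
  v <- array(0, c(nrow(mel), ncol(mel), 3L))
  v[, , 1L] <- mel; v[, , 2L] <- delta; v[, , 3L] <- delta2
  structure(list(values = v, frame_times = frame_times,
                 frame_params = frame_params),
            class = "feature_stack")
}

#' Full Mel/delta/delta-delta feature stack of a clip
#'
#' Convenience front-end: [mel_spectrogram()], then [delta_features()] and
#' its second application, stacked with [stack_channels()].
#'
#' @inheritParams mel_spectrogram
#' @param half_width delta regression half width in frames.
#' @return A `feature_stack`.
#' @export
feature_stack <- function(clip, n_mels = .N_MELS, half_width = 2L) {
  mel <- mel_spectrogram(clip, n_mels)
  d1 <- delta_features(mel, half_width)
  d2 <- delta_features(d1, half_width)
  stack_channels(mel, d1, d2)
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_stack> %d bands x %d frames x %d channels (hop %.2f ms)\n",
              d[1], d[2], d[3],
              1000 * x$frame_params$hop / x$frame_params$sample_rate))
  invisible(x)
}

#' Cut a feature stack into sliding 12-frame segments
#'
#' Sliding windows of 12 consecutive frames (100 ms of hops) starting every
#' `stride_frames` frames; `S = floor((T - 12)/stride) + 1` segments. Segment
#' start times are the start of the first window of the segment, so a
#' segment spans `[start, start + 12 * hop)` in hop terms.
#'
#' @param stack a `feature_stack`.
#' @param stride_frames stride between segment starts, 1-12 frames.
#' @return An object of class `segment_batch`: `segments` (bands x 12 x 3 x S
#'   array), `segment_start_times`, and empty label slots.
#' @export
segment_stack <- function(stack, stride_frames = 6L) {
  stopifnot(inherits(stack, "feature_stack"),
            stride_frames >= 1L, stride_frames <= .SEG_FRAMES)
  n_frames <- dim(stack$values)[2]
  if (n_frames < .SEG_FRAMES)
    stop("feature stack has ", n_frames, " frames; need at least ",
         .SEG_FRAMES, " for one segment")
  s <- (n_frames - .SEG_FRAMES) %/% stride_frames + 1L
  starts <- (seq_len(s) - 1L) * stride_frames          # 0-based frame index
  fp <- stack$frame_params
  seg <- array(0, c(dim(stack$values)[1], .SEG_FRAMES, 3L, s))
  for (i in seq_len(s))
    seg[, , , i] <- stack$values[, (starts[i] + 1L):(starts[i] + .SEG_FRAMES), ]
  structure(list(segments = seg,
                 segment_start_times = starts * fp$hop / fp$sample_rate,
                 labels_landing = NULL, labels_takeoff = NULL,
                 frame_params = fp),
            class = "segment_batch")
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$segments)
  lab <- if (is.null(x$labels_landing)) "unlabeled"
         else sprintf("%d landing+, %d takeoff+", sum(x$labels_landing),
                      sum(x$labels_takeoff))
  cat(sprintf("<segment_batch> %d segments of %dx%dx%d (%s)\n",
              d[4], d[1], d[2], d[3], lab))
  invisible(x)
}

#' Label segments against a ground-truth annotation
#'
#' A segment gets `labels_landing = 1` iff the annotated landing instant
#' falls in `[start, start + 12 * hop)`, and likewise for the take-off; all
#' other segments are 0.
#'
#' @param batch a `segment_batch`.
#' @param annotation a one-row data.frame with `takeoff_s` and `landing_s`.
#' @return The batch with `labels_landing` and `labels_takeoff` filled in.
#' @export
label_segments <- function(batch, annotation) {
  stopifnot(inherits(batch, "segment_batch"))
  fp <- batch$frame_params
  span <- .SEG_FRAMES * fp$hop / fp$sample_rate
  st <- batch$segment_start_times
  batch$labels_landing <- as.integer(annotation$landing_s >= st &
                                       annotation$landing_s < st + span)
  batch$labels_takeoff <- as.integer(annotation$takeoff_s >= st &
                                       annotation$takeoff_s < st + span)
  batch
}

# ---- Standardization -------------------------------------------------------

#' Per-channel standardization statistics
#'
#' Global mean and standard deviation of each of the three channels over a
#' training segment batch. The statistics travel with a trained detector and
#' are re-applied verbatim at inference; a clip is never standardized by its
#' own statistics.
#'
#' @param batch a `segment_batch` (training data).
#' @return A list with numeric vectors `mean` and `sd` of length 3.
#' @export
channel_stats <- function(batch) {
  stopifnot(inherits(batch, "segment_batch"))
  m <- numeric(3); s <- numeric(3)
  for (ch in 1:3) {
    v <- batch$segments[, , ch, ]
    m[ch] <- mean(v)
    s[ch] <- stats::sd(as.numeric(v))
    if (s[ch] == 0) s[ch] <- 1
  }
  list(mean = m, sd = s)
}

#' Apply stored standardization statistics
#'
#' @param x a `segment_batch` or `feature_stack`.
#' @param stats a list from [channel_stats()].
#' @return `x` with each channel centered and scaled by the stored values.
#' @export
apply_channel_stats <- function(x, stats) {
  if (inherits(x, "segment_batch")) {
    for (ch in 1:3)
      x$segments[, , ch, ] <- (x$segments[, , ch, ] - stats$mean[ch]) /
        stats$sd[ch]
  } else if (inherits(x, "feature_stack")) {
    for (ch in 1:3)
      x$values[, , ch] <- (x$values[, , ch] - stats$mean[ch]) / stats$sd[ch]
  } else stop("unsupported input")
  x
}
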