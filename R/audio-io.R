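#' Audio clip container
#'
#' Lightweight carrier for a mono waveform: a numeric vector of dimensionless
#' amplitudes (nominal range \[-1, 1\]) plus its sampling rate in Hz. Every
#' stage of the pipeline consumes and produces this object; the canonical
#' pipeline rate is 48 kHz, matching smartphone audio capture.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (positive integer).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @seealso [read_wav()], [write_wav()], [resample_to_48k()]
#' @export
audio_clip <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate, clip_duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an [audio_clip()].
#' @return Length in seconds (sample count / sample rate).
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

# ---- WAV (RIFF) reading/writing -------------------------------------------
# PCM16 and IEEE float32 are the encodings smartphone exports use; nothing
# else is accepted. No audio package is required: the chunked RIFF layout is
# parsed directly.

#' Read a WAV file as a mono audio clip
#'
#' Accepts RIFF/WAV files holding PCM16 or IEEE float32 samples with one or
#' two channels. Stereo files are averaged to mono (the capture scenario is a
#' single smartphone microphone). Amplitudes are returned in \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAV file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("truncated WAV file (no data chunk): ", path)
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0L) stop("truncated WAV file: ", path)
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                            endian = "little"),
        channels  = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                            endian = "little"),
        rate      = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits      = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                            endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      payload <- readBin(con, "raw", sz)
      if (length(payload) < sz) stop("truncated WAV data chunk: ", path)
      return(.decode_wav_data(payload, fmt, path))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (word-aligned)
    }
  }
}

.decode_wav_data <- function(payload, fmt, path) {
  if (!fmt$channels %in% c(1L, 2L))
    stop("unsupported WAV channel count (", fmt$channels, "): ", path)
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(payload, "integer", length(payload) %/% 2L, 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(payload, "double", length(payload) %/% 4L, 4L,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ",
         fmt$bits, " bit): ", path)
  }
  if (fmt$channels == 2L) {
    n <- length(x) %/% 2L
    x <- (x[seq(1L, 2L * n, by = 2L)] + x[seq(2L, 2L * n, by = 2L)]) / 2
  }
  audio_clip(x, fmt$rate)
}

#' Write an audio clip as PCM16 mono WAV
#'
#' The canonical emitted encoding is 16-bit PCM mono at the clip's own rate.
#' Amplitudes outside \[-1, 1\] are clipped to full scale with a warning.
#'
#' @param clip an [audio_clip()]; amplitudes must be finite.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!all(is.finite(clip$samples))) stop("non-finite amplitudes in clip")
  x <- clip$samples
  if (any(x > 1 | x < -1)) {
    warning("amplitudes outside [-1, 1] clipped to full scale")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write WAV file: ", path))
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + nbytes, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(clip$sample_rate, con, size = 4L, endian = "little")
  writeBin(clip$sample_rate * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample an audio clip to the canonical 48 kHz rate
#'
#' Polyphase resampling (via [signal::resample()]) to 48 kHz; a clip already
#' at 48 kHz is returned unchanged, so the operation is idempotent. Output
#' length is `round(n * 48000 / sample_rate)`, preserving duration to within
#' one sample.
#'
#' @param clip an [audio_clip()].
#' @return An [audio_clip()] at 48000 Hz.
#' @export
resample_to_48k <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate == 48000L) return(clip)
  g <- .gcd(48000L, clip$sample_rate)
  p <- 48000L %/% g
  q <- clip$sample_rate %/% g
  y <- signal::resample(clip$samples, p, q)
  n_out <- round(length(clip$samples) * 48000 / clip$sample_rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, numeric(n_out - length(y)))
  audio_clip(y, 48000L)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

# ---- Annotations -----------------------------------------------------------

#' Validate a take-off/landing annotation pair
#'
#' Enforces the physiological constraints on one jump: `0 <= takeoff <
#' landing`, flight time (landing - takeoff) at most 0.7 s, and, when the
#' clip duration is known, `landing <= duration`.
#'
#' @param takeoff_s,landing_s event instants in seconds from clip start.
#' @param duration_s optional clip duration in seconds.
#' @param what label used in error messages.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_annotation <- function(takeoff_s, landing_s, duration_s = NULL,
                                what = "annotation") {
  if (!is.finite(takeoff_s) || !is.finite(landing_s))
    stop(what, ": non-finite event time")
  if (takeoff_s < 0) stop(what, ": takeoff_s must be >= 0")
  if (landing_s <= takeoff_s)
    stop(what, ": landing (", landing_s, ") must be after take-off (",
         takeoff_s, ")")
  if (landing_s - takeoff_s > 0.7)
    stop(what, ": flight time ", round(landing_s - takeoff_s, 4),
         " s exceeds the 0.7 s physiological bound")
  if (!is.null(duration_s) && landing_s > duration_s)
    stop(what, ": landing at ", landing_s, " s is beyond clip end (",
         round(duration_s, 4), " s)")
  invisible(TRUE)
}

#' Read ground-truth jump annotations from CSV
#'
#' Expects a UTF-8 CSV with header `recording_id,takeoff_s,landing_s`
#' ('.' decimal separator), one row per recording, each row carrying the
#' take-off and landing instants in seconds from clip start. Every row is
#' validated with [validate_annotation()]; an invalid row aborts with a
#' message naming it.
#'
#' @param path path to the annotation CSV.
#' @return A data.frame with columns `recording_id`, `takeoff_s`,
#'   `landing_s` (possibly zero rows).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "takeoff_s", "landing_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have header recording_id,takeoff_s,landing_s: ",
         path)
  df <- df[, need]
  if (nrow(df)) {
    df$takeoff_s <- as.numeric(df$takeoff_s)
    df$landing_s <- as.numeric(df$landing_s)
    for (i in seq_len(nrow(df)))
      validate_annotation(df$takeoff_s[i], df$landing_s[i],
                          what = paste0("row ", i, " (", df$recording_id[i], ")"))
  }
  df
}

#' Write jump annotations to CSV
#' @param annotations data.frame with columns `recording_id`, `takeoff_s`,
#'   `landing_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  need <- c("recording_id", "takeoff_s", "landing_s")
  stopifnot(all(need %in% names(annotations)))
  utils::write.csv(annotations[, need], path, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}
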