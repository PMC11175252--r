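test_that("frame count follows the 800/400 window arithmetic", {
  clip <- audio_clip(stats::rnorm(48000), 48000L)
  mel <- mel_spectrogram(clip)
  expect_equal(ncol(mel), 119)
  expect_equal(nrow(mel), 128)
  ft <- attr(mel, "frame_times")
  expect_equal(unique(round(diff(ft), 10)), 400 / 48000)
  # time -> frame -> time round trip errs by at most half a hop
  t_query <- 0.5
  nearest <- ft[which.min(abs(ft - t_query))]
  expect_lte(abs(nearest - t_query), 0.5 * 400 / 48000 + 1e-12)
})

test_that("frame-count formula matches enumeration of window placements over the full sweep", {
  n <- 800:480000
  formula <- (n - 800L) %/% 400L + 1L
  # independent enumeration: window k (1-based) fits iff (k-1)*400 + 800 <= N
  window_ends <- 800L + 400L * (0L:1198L)
  enumerated <- findInterval(n, window_ends)
  expect_identical(formula, enumerated)
})

test_that("silent and tonal clips produce the expected Mel patterns", {
  silent <- audio_clip(numeric(48000), 48000L)
  mel <- mel_spectrogram(silent)
  expect_true(all(mel == -80))

  tone <- audio_clip(sin(2 * pi * 1000 * (0:47999) / 48000), 48000L)
  mt <- mel_spectrogram(tone)
  arg <- apply(mt, 2, which.max)
  expect_length(unique(arg), 1)
  # oracle: the band whose triangular filter weights the 1 kHz FFT bin most
  fb <- mel_filterbank()
  bin_1k <- which.min(abs((0:400) * 48000 / 800 - 1000))
  expect_equal(unique(arg), which.max(fb[, bin_1k]))
  expect_true(all(mt <= 0))

  expect_error(mel_spectrogram(audio_clip(numeric(100), 48000L)), "window")
  expect_error(mel_spectrogram(audio_clip(numeric(48000), 44100L)), "48 kHz")
})

test_that("regression deltas have the closed-form slope behavior", {
  const <- matrix(5, 16, 20)
  expect_true(all(delta_features(const) == 0))

  ramp <- matrix(rep(1:20, each = 16), 16, 20)
  d <- delta_features(ramp)
  expect_true(all(abs(d[, 3:18] - 1) < 1e-12))   # interior slope exactly 1

  set.seed(1)
  x <- matrix(rnorm(16 * 20), 16, 20)
  expect_equal(delta_features(-x), -delta_features(x))

  expect_error(delta_features(matrix(0, 4, 3)), "frames")
})

test_that("channel stacking validates shapes and keeps channels intact", {
  m <- matrix(rnorm(12 * 20), 12, 20)
  st <- stack_channels(m, m, m, frame_times = seq_len(20),
                       frame_params = list(window = 800, hop = 400,
                                           sample_rate = 48000))
  expect_true(all(st$values[, , 1] == st$values[, , 2]))
  expect_true(all(st$values[, , 1] == st$values[, , 3]))
  expect_error(stack_channels(m, m, matrix(0, 12, 19)), "shapes")
})

test_that("standardization uses stored statistics, never the clip's own", {
  recs <- make_dataset(3, easy_synth_config(1))
  batch <- recording_segments(recs, 12L)
  stats <- channel_stats(batch)
  std <- apply_channel_stats(batch, stats)
  for (ch in 1:3) {
    expect_lt(abs(mean(std$segments[, , ch, ])), 1e-6)
    expect_lt(abs(stats::sd(as.numeric(std$segments[, , ch, ])) - 1), 1e-6)
  }
  # a different batch standardized with these stats is NOT mean-0/sd-1
  other <- recording_segments(make_dataset(2, easy_synth_config(99)), 12L)
  std2 <- apply_channel_stats(other, stats)
  manual <- (other$segments[, , 1, ] - stats$mean[1]) / stats$sd[1]
  expect_equal(as.numeric(std2$segments[, , 1, ]), as.numeric(manual))
})

test_that("segment slicing follows S = floor((T - 12)/stride) + 1", {
  clip <- audio_clip(stats::rnorm(48000), 48000L)
  st <- feature_stack(clip)                      # T = 119
  expect_equal(dim(segment_stack(st, 12L)$segments)[4], 9)
  expect_equal(dim(segment_stack(st, 6L)$segments)[4], 18)
  sb <- segment_stack(st, 12L)
  expect_equal(sb$segments[, , , 1], st$values[, 1:12, ])

  st12 <- st; st12$values <- st$values[, 1:12, , drop = FALSE]
  st12$frame_times <- st$frame_times[1:12]
  expect_equal(dim(segment_stack(st12, 5L)$segments)[4], 1)
  st11 <- st12; st11$values <- st11$values[, 1:11, , drop = FALSE]
  expect_error(segment_stack(st11, 1L), "at least")
})

test_that("labeling marks exactly the segment containing each event", {
  # landing at the exact center of segment k
  rec <- clean_jump(flight = 0.4, seed = 2)
  batch <- segment_stack(feature_stack(rec$clip), 12L)
  ann <- rec$annotation
  lab <- label_segments(batch, ann)
  span <- 12 * 400 / 48000
  k <- which(lab$labels_landing == 1)
  expect_length(k, 1)
  expect_true(ann$landing_s >= lab$segment_start_times[k] &&
                ann$landing_s < lab$segment_start_times[k] + span)

  # event beyond the segmented span -> all zeros
  far <- ann; far$landing_s <- clip_duration(rec$clip) + 1
  far$takeoff_s <- clip_duration(rec$clip) + 0.6
  lab2 <- label_segments(batch, far)
  expect_true(all(lab2$labels_landing == 0) && all(lab2$labels_takeoff == 0))

  # exactly one positive landing segment per recording at stride 12
  cfg <- synth_config(background_kind = "none")
  for (seed in 1:100) {
    r <- synth_jump_recording(cfg, seed = seed)
    b <- label_segments(segment_stack(feature_stack(r$clip), 12L),
                        r$annotation)
    expect_equal(sum(b$labels_landing), 1)
  }
})

test_that("labeling is translation-consistent under a one-hop shift", {
  rec <- clean_jump(flight = 0.5, seed = 3)
  st <- feature_stack(rec$clip)
  b1 <- label_segments(segment_stack(st, 1L), rec$annotation)
  shifted <- audio_clip(c(numeric(400), rec$clip$samples), 48000L)
  ann2 <- rec$annotation
  ann2$takeoff_s <- ann2$takeoff_s + 400 / 48000
  ann2$landing_s <- ann2$landing_s + 400 / 48000
  b2 <- label_segments(segment_stack(feature_stack(shifted), 1L), ann2)
  i1 <- which(b1$labels_landing == 1)
  i2 <- which(b2$labels_landing == 1)
  expect_equal(i2, i1 + 1L)
})
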