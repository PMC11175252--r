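test_that("kinematics reproduce the standard flight-time/height relations", {
  # 30 cm jump <-> 495 ms flight, to the nearest millisecond
  expect_equal(round(flight_from_height(0.30) * 1000), 495)
  expect_equal(round(jump_height(0.495), 3), 0.300)
  # 7 ms timing error at 495 ms moves the height by 8.5 mm
  expect_equal(round(height_sensitivity(0.495, 0.007) * 1000, 1), 8.5)

  # monotonicity and closed-form inverse round trip
  t <- seq(0.05, 0.7, by = 0.01)
  h <- jump_height(t)
  expect_true(all(diff(h) > 0))
  expect_lt(max(abs(flight_from_height(h) - t)), 1e-9)

  ft <- flight_time_and_height(1.0, 1.495)
  expect_equal(ft$flight_s, 0.495)
  expect_equal(ft$height_m, 9.81 * 0.495^2 / 8)
  expect_error(flight_time_and_height(1, 1), "positive")
  expect_error(flight_time_and_height(1, 1.75), "0.7")
})

test_that("onset localization finds impulses and matches the generator truth", {
  x <- numeric(96000); x[48001] <- 1
  clip <- audio_clip(x, 48000L)
  on <- localize_onset(clip, 1.0)
  expect_lte(abs(on - 1.0), 0.001)

  # clean landing event: within 2 ms of the 1%-of-peak ground truth
  for (seed in c(1, 5, 9)) {
    rec <- clean_jump(flight = 0.45, seed = seed)
    truth <- rec$annotation$landing_s
    on2 <- localize_onset(rec$clip, truth + 0.01)  # detected segment nearby
    expect_lte(abs(on2 - truth), 0.002)
  }
})

test_that("onset localization is invariant to gain and appended silence", {
  rec <- clean_jump(flight = 0.4, seed = 4)
  center <- rec$annotation$landing_s + 0.01
  base <- as.numeric(localize_onset(rec$clip, center))
  louder <- audio_clip(rec$clip$samples * 10^(10 / 20), 48000L)
  expect_identical(as.numeric(localize_onset(louder, center)), base)
  padded <- audio_clip(c(rec$clip$samples, numeric(48000)), 48000L)
  expect_identical(as.numeric(localize_onset(padded, center)), base)

  expect_error(localize_onset(audio_clip(numeric(48000), 48000L), 0.5),
               "silent")
})

test_that("landing scan triggers on the jump and stays silent otherwise", {
  models <- tiny_trained_models()
  rec <- make_dataset(1, easy_synth_config(77), id_prefix = "scan")[[1]]
  stack <- feature_stack(rec$clip)
  hit <- scan_for_landing(stack, models$landing, 4L, 0.5)
  expect_false(is.null(hit))
  expect_lte(abs(hit$time - rec$annotation$landing_s), 0.05)
  expect_gte(hit$confidence, 0.5)

  # probability can never exceed 1, so an impossible threshold yields none
  expect_null(scan_for_landing(stack, models$landing, 4L, 1.01))
})

test_that("take-off search is confined to the physiological window", {
  models <- tiny_trained_models()
  rec <- make_dataset(1, easy_synth_config(78), id_prefix = "srch")[[1]]
  stack <- feature_stack(rec$clip)
  landing <- rec$annotation$landing_s
  hit <- search_for_takeoff(stack, models$takeoff, landing)
  expect_false(is.null(hit))
  expect_lte(abs(hit$time - rec$annotation$takeoff_s), 0.05)
  # any candidate lies fully inside [landing - 0.7, landing - 0.15]
  expect_gte(hit$segment_start, landing - 0.7)
  expect_lte(hit$segment_start + 0.1, landing - 0.15)

  expect_error(search_for_takeoff(stack, models$takeoff, 0.05), "take-off")
})

test_that("detect_jump composes the stages and degrades gracefully", {
  models <- tiny_trained_models()
  rec <- clean_jump(flight = 0.495, seed = 12)
  det <- detect_jump(rec$clip, models$landing, models$takeoff,
                     recording_id = rec$id)
  expect_equal(det$status, "ok")
  expect_lte(abs(det$flight_s - 0.495), 0.007)
  expect_equal(det$height_m, 9.81 * det$flight_s^2 / 8)

  det2 <- detect_jump(rec$clip, models$landing, models$takeoff)
  expect_identical(det[names(det) != "recording_id"],
                   det2[names(det2) != "recording_id"])   # deterministic

  # jump-free audio: the trigger/quality-gate combination keeps the
  # pipeline silent regardless of spurious detector activations
  for (s in c(50, 123, 31)) {
    bg <- synth_background(4, synth_config(), seed = s)
    miss <- detect_jump(bg, models$landing, models$takeoff)
    expect_equal(miss$status, "no_landing")
    expect_true(is.na(miss$flight_s) && is.na(miss$height_m))
  }

  # silencing the take-off leaves a landing-only recording
  muted <- rec$clip
  cut0 <- round((rec$annotation$takeoff_s - 0.02) * 48000)
  cut1 <- round((rec$annotation$takeoff_s + 0.1) * 48000)
  muted$samples[cut0:cut1] <- 0
  det3 <- detect_jump(muted, models$landing, models$takeoff)
  expect_equal(det3$status, "no_takeoff")
  expect_true(is.na(det3$flight_s))
})
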