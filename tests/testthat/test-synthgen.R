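test_that("event synthesizers respect the 50-80 ms duration bound", {
  cfg <- synth_config()
  for (seed in 1:100) {
    to <- synth_takeoff_event(cfg, seed = seed)
    la <- synth_landing_event(cfg, seed = seed)
    expect_gte(to$duration, 0.05); expect_lte(to$duration, 0.08)
    expect_gte(la$duration, 0.05); expect_lte(la$duration, 0.08)
    # above-1%-of-peak support cannot exceed the nominal duration by a bin
    supp <- range(which(abs(to$clip$samples) > 0.01 * max(abs(to$clip$samples))))
    expect_lte(diff(supp) / 48000, to$duration + 0.001)
  }
})

test_that("event synthesis is deterministic under a seed and varies across seeds", {
  cfg <- synth_config()
  a <- synth_takeoff_event(cfg, seed = 1)
  b <- synth_takeoff_event(cfg, seed = 1)
  expect_identical(a$clip$samples, b$clip$samples)
  c2 <- synth_takeoff_event(cfg, seed = 2)
  expect_false(isTRUE(all.equal(a$clip$samples[1:1000], c2$clip$samples[1:1000])))
})

test_that("landing is louder and darker than take-off", {
  cfg <- synth_config()
  rms <- function(x) sqrt(mean(x^2))
  centroid <- function(x) {
    sp <- Mod(stats::fft(x))^2
    n <- length(x)
    f <- (seq_len(n %/% 2) - 1) * 48000 / n
    sum(f * sp[seq_len(n %/% 2)]) / sum(sp[seq_len(n %/% 2)])
  }
  for (seed in 1:50) {
    to <- synth_takeoff_event(cfg, seed = seed)
    la <- synth_landing_event(cfg, seed = seed)
    ratio <- rms(la$clip$samples) / rms(to$clip$samples)
    expect_equal(ratio, cfg$landing_to_takeoff_level_ratio, tolerance = 0.05)
    expect_lt(centroid(la$clip$samples), centroid(to$clip$samples))
  }
})

test_that("background noise is steady and low-frequency weighted", {
  cfg <- synth_config()
  bg <- synth_background(2, cfg, seed = 3)
  expect_length(bg$samples, 96000)
  sp <- Mod(stats::fft(bg$samples))^2
  f <- (seq_along(sp) - 1) * 48000 / length(sp)
  half <- f <= 24000
  expect_gte(sum(sp[half & f < 1000]) / sum(sp[half]), 0.6)
  rms <- function(x) sqrt(mean(x^2))
  first <- rms(bg$samples[1:24000])
  last <- rms(bg$samples[72001:96000])
  expect_lt(abs(20 * log10(first / last)), 3)
})

test_that("impulsive interference follows its Poisson placement contract", {
  cfg <- synth_config(impulse_rate = 0)
  z <- synth_impulses(2, cfg, seed = 1)
  expect_true(all(z$clip$samples == 0))
  expect_length(z$impulse_times, 0)

  cfg2 <- synth_config(impulse_rate = 2)
  counts <- vapply(1:200, function(s)
    length(synth_impulses(10, cfg2, seed = s)$impulse_times), 0)
  # Poisson(20): mean within 3 standard errors
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 200))
  times <- synth_impulses(10, cfg2, seed = 5)$impulse_times
  expect_true(all(times >= 0 & times < 10))
})

test_that("mix_at_snr realizes the requested SNR exactly", {
  event <- audio_clip(c(1, numeric(999)), 48000L)
  noise <- audio_clip(rep(c(1, -1), 500), 48000L)   # unit RMS
  mixed <- mix_at_snr(event, noise, 20)
  # alpha = peak * 10^(-snr/20) / rms = 0.1, closed form
  expect_equal((mixed$samples - event$samples) / noise$samples,
               rep(0.1, 1000))
  alpha_noise <- mixed$samples - event$samples
  snr_meas <- 20 * log10(max(abs(event$samples)) / sqrt(mean(alpha_noise^2)))
  expect_equal(snr_meas, 20, tolerance = 0.01)

  expect_identical(mix_at_snr(event, noise, Inf), event)
  silent <- audio_clip(numeric(1000), 48000L)
  expect_error(mix_at_snr(event, silent, 10), "zero RMS")
})

test_that("synthetic recordings carry exact sample-grid annotations", {
  cfg <- synth_config(flight_time_range = c(0.495, 0.495))
  rec <- synth_jump_recording(cfg, seed = 7)
  expect_equal(rec$annotation$landing_s - rec$annotation$takeoff_s, 0.495)

  # clean track: annotated onsets match the 1%-of-peak convention within 1 ms
  clean_cfg <- synth_config(background_kind = "none")
  rec2 <- synth_jump_recording(clean_cfg, seed = 3)
  x <- rec2$clip$samples
  first <- (which(abs(x) > 0.01 * max(abs(x)))[1] - 1) / 48000
  expect_lt(abs(first - rec2$annotation$takeoff_s), 0.001)

  for (seed in 1:30) {
    r <- synth_jump_recording(synth_config(), seed = seed)
    fl <- r$annotation$landing_s - r$annotation$takeoff_s
    expect_gte(fl, 0.30 - 1e-4); expect_lte(fl, 0.70 + 1e-4)
    comp <- r$components
    expect_lt(max(abs(r$clip$samples -
                        (comp$clean$samples + comp$background$samples +
                           comp$impulses$samples))), 1e-6)
  }
})

test_that("dataset generation is bitwise deterministic under its seed", {
  cfg <- synth_config(seed = 9)
  d1 <- make_dataset(3, cfg)
  d2 <- make_dataset(3, cfg)
  expect_identical(lapply(d1, `[[`, "clip"), lapply(d2, `[[`, "clip"))
  expect_identical(lapply(d1, `[[`, "annotation"), lapply(d2, `[[`, "annotation"))
})

test_that("augmented twins share events and annotations but not noise", {
  cfg <- synth_config(seed = 4)
  d <- make_dataset(4, cfg, augment = TRUE)
  expect_length(d, 8)
  for (i in seq(1, 8, by = 2)) {
    base <- d[[i]]; twin <- d[[i + 1]]
    expect_equal(twin$base_id, base$id)
    expect_equal(twin$annotation$takeoff_s, base$annotation$takeoff_s)
    expect_equal(twin$annotation$landing_s, base$annotation$landing_s)
    # identical clean events up to the per-recording full-scale gain
    bc <- base$components$clean$samples
    tc <- twin$components$clean$samples
    expect_equal(tc / max(abs(tc)), bc / max(abs(bc)), tolerance = 1e-12)
    r <- cor(twin$components$background$samples,
             base$components$background$samples)
    expect_lt(abs(r), 0.2)
  }
})

test_that("spliced jumps realize the imposed gap exactly", {
  cfg <- synth_config()
  to <- synth_takeoff_event(cfg, seed = 1)
  la <- synth_landing_event(cfg, seed = 2)
  sp <- splice_synthetic_jump(to, la, 0.400)
  expect_equal(sp$annotation$landing_s - sp$annotation$takeoff_s, 0.400)

  sp2 <- splice_synthetic_jump(to, la, 0.495)
  sep <- round((sp2$annotation$landing_s - sp2$annotation$takeoff_s) * 48000)
  expect_equal(sep, 23760)
  # the waveform's own 1%-onsets are the annotated ones
  x <- sp2$clip$samples
  on1 <- which(abs(x) > 0.01 * max(abs(x)))[1]
  expect_lt(abs((on1 - 1) / 48000 - sp2$annotation$takeoff_s), 0.001)

  expect_error(splice_synthetic_jump(to, la, 0.8), "0.7")
  expect_error(splice_synthetic_jump(to, la, 0), "0.7")
})

test_that("dataset writer emits WAVs, annotations and a manifest", {
  out <- withr::local_tempdir()
  cfg <- synth_config(seed = 2, duration_range = c(3, 3.5))
  recs <- make_dataset(2, cfg, augment = TRUE)
  write_dataset(recs, out)
  expect_length(list.files(out, pattern = "\\.wav$"), 4)
  ann <- read_annotations(file.path(out, "annotations.csv"))
  expect_equal(nrow(ann), 4)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$n_recordings, 4)
})
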