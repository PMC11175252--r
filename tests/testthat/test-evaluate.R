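test_that("the false-positive window is closed at its boundary", {
  expect_false(is_false_positive(1.049, 1.000))
  expect_true(is_false_positive(1.051, 1.000))
  expect_false(is_false_positive(1.050, 1.000))   # exactly on the boundary
  expect_error(is_false_positive(1, 1, tolerance = -0.1), "non-negative")
})

.fake_detection <- function(id, takeoff, landing, status = "ok") {
  structure(list(recording_id = id, status = status,
                 takeoff_onset = if (status == "ok") takeoff else NA_real_,
                 landing_onset = if (status == "no_landing") NA_real_ else landing,
                 flight_s = if (status == "ok") landing - takeoff else NA_real_,
                 height_m = if (status == "ok") jump_height(landing - takeoff)
                            else NA_real_,
                 landing_confidence = 0.9, takeoff_confidence = 0.9),
            class = "jump_detection")
}

test_that("false-positive accounting reproduces the percentage arithmetic", {
  n <- 216
  truths <- data.frame(recording_id = sprintf("r%03d", 1:n),
                       takeoff_s = rep(1, n), landing_s = rep(1.4, n))
  preds <- lapply(1:n, function(i)
    .fake_detection(sprintf("r%03d", i), 1,
                    if (i <= 57) 1.4 + 0.2 else 1.4))
  rep <- summarize_detections(truths, preds)
  expect_equal(rep$n_false_positives, 57)
  expect_equal(rep$fp_percent, 26.39)
  expect_equal(rep$n_missed, 0)

  # permutation invariance in recording order
  rep2 <- summarize_detections(truths, rev(preds))
  expect_equal(rep2$fp_percent, rep$fp_percent)
  expect_equal(rep2$mean_abs_error, rep$mean_abs_error)

  # fp_percent recomputation is exact over a grid of (FP, N)
  for (N in c(10, 57, 100, 216)) for (fp in c(0, 1, N %/% 3, N))
    expect_equal(round(100 * fp / N, 2),
                 summarize_detections(
                   truths[1:N, ],
                   lapply(1:N, function(i)
                     .fake_detection(sprintf("r%03d", i), 1,
                                     if (i <= fp) 1.6 else 1.4)))$fp_percent)
})

test_that("error statistics are computed over ok detections only", {
  truths <- data.frame(recording_id = c("a", "b", "c"),
                       takeoff_s = c(1, 1, 1), landing_s = c(1.4, 1.4, 1.4))
  preds <- list(.fake_detection("a", 1, 1.405),             # +5 ms
                .fake_detection("b", 1.005, 1.4),           # -5 ms
                .fake_detection("c", NA, NA, "no_landing"))
  rep <- summarize_detections(truths, preds)
  expect_equal(rep$mean_abs_error, 0.005)
  expect_equal(rep$n_missed, 1)
  expect_equal(rep$n_false_positives, 0)

  perfect <- list(.fake_detection("a", 1, 1.4), .fake_detection("b", 1, 1.4),
                  .fake_detection("c", 1, 1.4))
  rep2 <- summarize_detections(truths, perfect)
  expect_equal(rep2$mean_abs_error, 0)
  expect_equal(rep2$n_false_positives, 0)

  expect_error(summarize_detections(truths, preds[1:2]), "unmatched")
  expect_error(summarize_detections(truths,
                                    c(preds, list(.fake_detection("zz", 1, 1.4)))),
               "zz")
})

test_that("the naive energy baseline handles clean jumps and silence", {
  rec <- clean_jump(flight = 0.5, seed = 21)
  det <- naive_energy_baseline(rec$clip, rec$id)
  expect_equal(det$status, "ok")
  expect_lte(abs(det$landing_onset - rec$annotation$landing_s), 0.05)
  expect_lte(abs(det$flight_s - 0.5), 0.05)

  silent <- audio_clip(numeric(48000), 48000L)
  expect_equal(naive_energy_baseline(silent)$status, "no_landing")

  # deterministic
  det2 <- naive_energy_baseline(rec$clip, rec$id)
  expect_identical(det, det2)
})

test_that("spliced-jump benchmark recovers imposed gaps monotonically", {
  models <- tiny_trained_models()
  cfg <- synth_config()
  library_pairs <- lapply(1:2, function(i)
    list(takeoff = synth_takeoff_event(cfg, seed = 30 + i),
         landing = synth_landing_event(cfg, seed = 60 + i)))
  gaps <- c(0.3, 0.4, 0.5, 0.6)
  bench <- benchmark_synthetic(library_pairs, gaps, models$landing,
                               models$takeoff)
  expect_equal(nrow(bench), 8)
  expect_equal(sort(unique(bench$imposed_gap_s)),
               round(gaps * 48000) / 48000)
  ok <- bench$status == "ok"
  expect_gte(mean(ok), 0.5)
  for (p in unique(bench$pair)) {
    rows <- bench[bench$pair == p & ok, ]
    if (nrow(rows) >= 3)
      expect_equal(cor(rows$imposed_gap_s, rows$recovered_gap_s,
                       method = "spearman"), 1)
  }
})
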