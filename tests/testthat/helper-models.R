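# Shared fixtures built in code. The small trained detector pair is built
# lazily once per test run (a deliberately reduced architecture on an easy,
# high-SNR synthetic dataset) and reused by the detection/CLI tests.

.fixture_env <- new.env(parent = emptyenv())

tiny_spec <- function() {
  detector_spec(conv_block_filters = c(4L, 8L, 16L),
                dense_widths = c(64L, 16L),
                param_range = c(1e3, 1e6))
}

tiny_train_config <- function(epochs = 10L, seed = 7L) {
  train_config(epochs = epochs, early_stop_patience = epochs - 1L,
               batch_size = 64L, seed = seed)
}

# favorable conditions: moderate background, few impulses. The SNR range
# reaches down to +5 dB so a model trained on it must key on event shape,
# not on a clip's absolute level.
easy_synth_config <- function(seed = 42L) {
  synth_config(seed = seed, snr_db = c(20, 10, 5), impulse_rate = 0.2,
               duration_range = c(3, 4))
}

tiny_trained_models <- function() {
  if (!is.null(.fixture_env$models)) return(.fixture_env$models)
  recs <- make_dataset(60, easy_synth_config(), augment = FALSE)
  tc <- tiny_train_config(epochs = 20L, seed = 7L)
  fits <- train_jump_detectors(recs, tc, tiny_spec(), stride_frames = 6L,
                               n_hard = 3L, n_random = 3L,
                               n_background = 10L,
                               synth_cfg = easy_synth_config())
  .fixture_env$models <- list(landing = fits$landing, takeoff = fits$takeoff,
                              recordings = recs)
  .fixture_env$models
}

# a clean (noise-free) jump recording with a prescribed flight time
clean_jump <- function(flight = 0.4, seed = 1L) {
  cfg <- synth_config(background_kind = "none",
                      flight_time_range = c(flight, flight),
                      duration_range = c(3, 4))
  synth_jump_recording(cfg, seed = seed, id = sprintf("clean_%d", seed))
}
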