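test_that("the default detector sits in the intended parameter budget", {
  m <- build_detector(seed = 1)
  expect_gte(n_params(m), 8e5)
  expect_lte(n_params(m), 1.05e6)
  # the guard trips when an architecture drifts from the budget
  small <- detector_spec(dense_widths = c(32L, 16L))
  expect_error(build_detector(small, seed = 1), "parameters")
})

test_that("forward passes are sigmoid-bounded and seed-reproducible", {
  m <- build_detector(tiny_spec(), seed = 3)
  set.seed(10)
  X <- array(rnorm(128 * 12 * 3 * 7), c(128, 12, 3, 7))
  p1 <- predict(m, X, standardize = FALSE)
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- predict(build_detector(tiny_spec(), seed = 3), X, standardize = FALSE)
  expect_identical(p1, p2)
  expect_error(predict(m, array(0, c(64, 12, 3, 2)), standardize = FALSE),
               "input")
})

test_that("analytic gradients match finite differences through every layer", {
  spec <- detector_spec(conv_block_filters = c(2L, 4L, 8L), dropout_rate = 0,
                        dense_widths = c(16L, 8L), param_range = c(1, 1e6))
  m <- build_detector(spec, seed = 5)
  set.seed(6)
  X <- array(rnorm(128 * 12 * 3 * 6), c(128, 12, 3, 6))
  y <- rbinom(6, 1, 0.5)
  fw <- soundjump:::.cnn_forward(m, X, train = TRUE)
  gr <- soundjump:::.cnn_backward(m, fw, y)
  loss_at <- function(model)
    soundjump:::.bce_loss(soundjump:::.cnn_forward(model, X, train = TRUE)$prob, y)
  set.seed(7)
  for (nm in names(gr)) {
    for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      eps <- 1e-5
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      # 1% relative: finite differences cross ReLU kinks occasionally
      expect_equal(gr[[nm]][i], num, tolerance = 1e-2,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("precision/recall/F1 identities hold for arbitrary count triples", {
  set.seed(42)
  for (rep in 1:200) {
    tp <- rpois(1, 20); fp <- rpois(1, 5); fn <- rpois(1, 5)
    m <- classification_metrics(tp, fp, fn)
    # brute-force oracle straight from the definitions
    p_ref <- if (tp + fp > 0) tp / (tp + fp) else 0
    r_ref <- if (tp + fn > 0) tp / (tp + fn) else 0
    f_ref <- if (p_ref + r_ref > 0) 2 * p_ref * r_ref / (p_ref + r_ref) else 0
    expect_identical(m$precision, p_ref)
    expect_identical(m$recall, r_ref)
    expect_identical(m$f1, f_ref)
    if (m$precision > 0 && m$recall > 0) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
  expect_equal(classification_metrics(0, 0, 5), list(precision = 0, recall = 0, f1 = 0))
  expect_equal(classification_metrics(7, 7, 7)$f1, 0.5)  # P = R = p -> F1 = p
  expect_error(classification_metrics(-1, 0, 0), "non-negative")
})

test_that("training learns a separable toy problem and early-stops", {
  s <- 200L
  seg <- array(0, c(128, 12, 3, s))
  y <- rep(c(1L, 0L), s / 2)
  seg[, , , y == 1] <- 1
  batch <- structure(list(segments = seg, segment_start_times = numeric(s),
                          labels_landing = y, labels_takeoff = y,
                          frame_params = list(window = 800, hop = 400,
                                              sample_rate = 48000)),
                     class = "segment_batch")
  tc <- train_config(epochs = 40, early_stop_patience = 10, seed = 2)
  m <- train_detector(build_detector(tiny_spec(), seed = 2), batch,
                      "landing", tc)
  expect_true(m$trained)
  expect_equal(max(m$history$val_precision), 1)
  expect_lte(nrow(m$history), 40)
  # once precision and recall saturate, patience stops training early
  expect_lt(nrow(m$history), 40)

  # single-class data is rejected
  bad <- batch; bad$labels_landing <- rep(0L, s)
  expect_error(train_detector(build_detector(tiny_spec(), seed = 2),
                              bad, "landing", tc), "single class")
})

test_that("trained detectors survive a save/load round trip", {
  models <- tiny_trained_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(models$landing, path)
  back <- load_detector(path)
  set.seed(11)
  X <- array(rnorm(128 * 12 * 3 * 4), c(128, 12, 3, 4))
  expect_identical(predict(back, X), predict(models$landing, X))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$target, "landing")
  expect_equal(side$n_params, n_params(models$landing))
})

test_that("detectors reach high precision and recall on favorable-SNR data", {
  # scaled-down check: evaluated on held-out recordings at >= +10 dB SNR
  models <- tiny_trained_models()
  cfg <- synth_config(seed = 314, snr_db = c(20, 15, 10), impulse_rate = 0.2,
                      duration_range = c(3, 4))
  held <- make_dataset(10, cfg, id_prefix = "held")
  batch <- recording_segments(held, 6L, n_hard = 2L, n_random = 2L, seed = 9)
  for (target in c("landing", "takeoff")) {
    y <- if (target == "landing") batch$labels_landing else batch$labels_takeoff
    pr <- predict(models[[target]], batch)
    calls <- as.integer(pr >= 0.5)
    m <- classification_metrics(sum(calls & y), sum(calls & !y),
                                sum(!calls & y))
    expect_gte(m$precision, 0.9)
    expect_gte(m$recall, 0.9)
  }
})

test_that("k-fold cross-validation partitions by recording and averages metrics", {
  recs <- make_dataset(10, easy_synth_config(5), augment = TRUE)
  batch <- recording_segments(recs, 6L, n_hard = 2L, n_random = 2L, seed = 3)
  tc <- train_config(epochs = 2, early_stop_patience = 1, k_folds = 5L,
                     seed = 3)
  cv <- kfold_cv(batch, "landing", tiny_spec(), tc)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(unname(cv$means["precision"]), mean(cv$folds$precision))
  expect_equal(unname(cv$means["f1"]), mean(cv$folds$f1))
  # folds partition base recordings evenly; twins share their base's fold
  sizes <- table(cv$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sort(names(cv$fold_assignment)),
               sort(unique(batch$base_id)))
  expect_error(kfold_cv(batch, "landing", tiny_spec(),
                        train_config(epochs = 2, early_stop_patience = 1,
                                     k_folds = 20L)),
               "at least")
})
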