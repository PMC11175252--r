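# Glue between recordings and detector training: feature extraction over
# whole recordings, labeled segment pooling, and negative subsampling.

#' Labeled segments of a set of recordings
#'
#' Computes the Mel/delta/delta-delta stack of each recording, cuts it into
#' 12-frame segments every `stride_frames` frames, labels them against the
#' recording's annotation, and pools everything into one `segment_batch`
#' carrying `recording_id` and `base_id` per segment (augmented twins share
#' their base recording's `base_id`, which fold partitioning relies on).
#'
#' @param recordings list of `synthetic_recording`s, or of lists with
#'   elements `id`, `clip`, `annotation` (one-row data.frame), and
#'   optionally `base_id`.
#' @param stride_frames stride between segment starts (6 = 50% segment
#'   overlap, enriching positives for training).
#' @param n_hard,n_random when given, each recording's negatives are
#'   subsampled immediately (see [subsample_segments()]) so that large
#'   datasets never hold their full segment sets in memory.
#' @param seed RNG seed for the per-recording random negative picks.
#' @return A labeled `segment_batch`.
#' @export
recording_segments <- function(recordings, stride_frames = 6L,
                               n_hard = NULL, n_random = NULL, seed = 1L) {
  pieces <- vector("list", length(recordings))
  for (k in seq_along(recordings)) {
    rec <- recordings[[k]]
    st <- feature_stack(rec$clip)
    sb <- segment_stack(st, stride_frames)
    sb <- label_segments(sb, rec$annotation)
    sb$recording_id <- rep(rec$id, dim(sb$segments)[4])
    sb$base_id <- rep(if (is.null(rec$base_id)) rec$id else rec$base_id,
                      dim(sb$segments)[4])
    if (!is.null(n_hard))
      sb <- subsample_segments(sb, n_hard,
                               if (is.null(n_random)) n_hard else n_random,
                               seed = seed + k)
    pieces[[k]] <- sb
  }
  .bind_batches(pieces)
}

.bind_batches <- function(pieces) {
  sizes <- vapply(pieces, function(p) dim(p$segments)[4], 0L)
  total <- sum(sizes)
  d <- dim(pieces[[1]]$segments)
  seg <- array(0, c(d[1], d[2], d[3], total))
  off <- 0L
  for (p in pieces) {
    k <- dim(p$segments)[4]
    if (k) seg[, , , (off + 1L):(off + k)] <- p$segments
    off <- off + k
  }
  structure(list(segments = seg,
                 segment_start_times = unlist(lapply(pieces, `[[`,
                                                     "segment_start_times")),
                 labels_landing = unlist(lapply(pieces, `[[`, "labels_landing")),
                 labels_takeoff = unlist(lapply(pieces, `[[`, "labels_takeoff")),
                 recording_id = unlist(lapply(pieces, `[[`, "recording_id")),
                 base_id = unlist(lapply(pieces, `[[`, "base_id")),
                 frame_params = pieces[[1]]$frame_params),
            class = "segment_batch")
}

#' Subsample negatives per recording for detector training
#'
#' Keeps every positive segment (for either event) and, per recording, a
#' deterministic mix of negatives: the highest-energy non-event segments
#' (hard negatives — impulsive interference lives there) plus random ones.
#' Negatives whose window overlaps a positive segment's span are excluded
#' from the candidate pool: a window starting just after an event onset
#' still contains most of the event's energy, and labeling it negative by
#' the onset-containment rule would inject systematic label noise into
#' training. This keeps the training set compact without discarding the
#' class the detectors must learn to reject.
#'
#' @param batch a labeled `segment_batch` with `recording_id`.
#' @param n_hard,n_random hard/random negatives kept per recording.
#' @param seed RNG seed for the random picks.
#' @return The subsampled `segment_batch`.
#' @export
subsample_segments <- function(batch, n_hard = 4L, n_random = 4L, seed = 1L) {
  stopifnot(!is.null(batch$recording_id))
  set.seed(seed)
  pos <- batch$labels_landing == 1L | batch$labels_takeoff == 1L
  fp <- batch$frame_params
  span <- 12 * fp$hop / fp$sample_rate
  # mean channel-0 level as a cheap energy proxy per segment
  s <- dim(batch$segments)[4]
  lev <- colMeans(matrix(batch$segments[, , 1L, ],
                         nrow = prod(dim(batch$segments)[1:2]), ncol = s))
  keep <- logical(s)
  keep[pos] <- TRUE
  for (id in unique(batch$recording_id)) {
    in_rec <- batch$recording_id == id
    pos_starts <- batch$segment_start_times[in_rec & pos]
    cand <- which(in_rec & !pos)
    if (length(pos_starts))                  # drop event-overlapping windows
      cand <- cand[vapply(batch$segment_start_times[cand], function(st)
        all(abs(st - pos_starts) >= span), TRUE)]
    if (!length(cand)) next
    hard <- cand[order(lev[cand], decreasing = TRUE)][seq_len(min(n_hard,
                                                                  length(cand)))]
    rest <- setdiff(cand, hard)
    rnd <- if (length(rest)) sample(rest, min(n_random, length(rest))) else integer()
    keep[c(hard, rnd)] <- TRUE
  }
  .subset_batch(batch, keep)
}

#' Segments from background-only (no-jump) clips
#'
#' Generates clips holding only background noise (and impulsive
#' interference, per the configuration) and returns a small set of all-zero
#' labeled segments per clip. Because the Mel front-end references decibels
#' to each clip's own maximum, a recording without any jump looks unlike
#' the quiet stretches of a jump recording; exposing the detectors to such
#' clips during training is what teaches them to stay silent on them.
#'
#' @param n_clips number of background-only clips.
#' @param config a [synth_config()] (its background/impulse settings are
#'   used).
#' @param stride_frames segmentation stride.
#' @param per_clip segments kept per clip (half highest-energy, half
#'   random).
#' @param seed RNG seed.
#' @return A labeled `segment_batch` with all labels zero.
#' @export
background_segments <- function(n_clips, config = synth_config(),
                                stride_frames = 6L, per_clip = 4L,
                                seed = 1L) {
  stopifnot(n_clips > 0)
  pieces <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    set.seed(seed + i)
    dur <- stats::runif(1, config$duration_range[1], config$duration_range[2])
    x <- synth_background(dur, config)$samples
    if (config$background_kind == "steady_plus_impulses")
      x <- x + synth_impulses(dur, config)$clip$samples[seq_along(x)]
    clip <- audio_clip(x / max(1, max(abs(x)) / 0.99), config$sample_rate)
    sb <- segment_stack(feature_stack(clip), stride_frames)
    s <- dim(sb$segments)[4]
    lev <- colMeans(matrix(sb$segments[, , 1L, ],
                           nrow = prod(dim(sb$segments)[1:2]), ncol = s))
    n_hard <- min(s, ceiling(per_clip / 2))
    hard <- order(lev, decreasing = TRUE)[seq_len(n_hard)]
    rest <- setdiff(seq_len(s), hard)
    keep <- c(hard, if (length(rest)) sample(rest, min(length(rest),
                                                       per_clip - n_hard)))
    sb$labels_landing <- integer(s)
    sb$labels_takeoff <- integer(s)
    id <- sprintf("bg%04d", i)
    sb$recording_id <- rep(id, s)
    sb$base_id <- rep(id, s)
    pieces[[i]] <- .subset_batch(sb, seq_len(s) %in% keep)
  }
  .bind_batches(pieces)
}

#' Train the landing and take-off detectors on a set of recordings
#'
#' End-to-end trainer: extracts labeled segments ([recording_segments()]),
#' subsamples negatives ([subsample_segments()]), and trains one binary
#' detector per event with [train_detector()]. Both detectors share the
#' segment pool and standardization statistics are fitted independently per
#' detector on its training split.
#'
#' @param recordings list of recordings (see [recording_segments()]).
#' @param config a [train_config()].
#' @param spec a [detector_spec()].
#' @param stride_frames training segmentation stride.
#' @param n_hard,n_random negatives kept per recording.
#' @param n_background background-only clips added as pure negatives (see
#'   [background_segments()]); defaults to 10% of the recordings.
#' @param synth_cfg generator configuration for the background-only clips.
#' @param quiet suppress progress.
#' @return A list with `landing` and `takeoff` `jump_cnn`s and the pooled
#'   `batch`.
#' @export
train_jump_detectors <- function(recordings, config = train_config(),
                                 spec = detector_spec(), stride_frames = 6L,
                                 n_hard = 4L, n_random = 4L,
                                 n_background = ceiling(0.1 * length(recordings)),
                                 synth_cfg = synth_config(), quiet = TRUE) {
  batch <- recording_segments(recordings, stride_frames, n_hard, n_random,
                              seed = config$seed)
  if (n_background > 0) {
    bg <- background_segments(n_background, synth_cfg, stride_frames,
                              per_clip = n_hard + n_random,
                              seed = config$seed + 7919L)
    batch <- .bind_batches(list(batch, bg))
  }
  landing <- build_detector(spec, seed = config$seed)
  landing <- train_detector(landing, batch, "landing", config, quiet = quiet)
  takeoff <- build_detector(spec, seed = config$seed + 1L)
  takeoff <- train_detector(takeoff, batch, "takeoff", config, quiet = quiet)
  list(landing = landing, takeoff = takeoff, batch = batch)
}
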