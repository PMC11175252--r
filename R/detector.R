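# Binary convolutional jump-event detectors.
#
# Two independent binary CNNs — one for landings, one for take-offs — each
# classifying a 128 x 12 x 3 Mel/delta/delta-delta segment as containing its
# event or not. Architecture: three convolutional blocks of 16/32/64 filters
# (each block: conv+ReLU, batch norm, conv+ReLU, dropout 0.25, 2x2 average
# pool), a flatten, a 768-unit dense layer with PReLU, dropout and batch
# norm, a 64-unit linear layer, and a single sigmoid output — about 9e5
# trainable parameters. Trained with binary cross-entropy and Adam,
# early-stopping on held-out precision. The convolution/pooling kernels live
# in src/convnet.cpp; everything else is plain R on BLAS.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

#' Architecture specification for a jump-event detector
#'
#' @param conv_block_filters filters per convolutional block (doubling per
#'   block; default 16, 32, 64).
#' @param convs_per_block convolution layers per block (2, the enumerated
#'   sequence; 3 available).
#' @param kernel 2-D convolution kernel size (odd, 'same' padding).
#' @param dropout_rate dropout rate after each block and in the dense head.
#' @param dense_widths widths of the two dense layers (first with PReLU,
#'   second linear).
#' @param input_shape bands x frames x channels of one segment.
#' @param param_range admissible trainable-parameter count; the default
#'   guards the roughly 900,000-parameter budget of the reference design
#'   against accidental drift. Relax it for deliberately small test networks.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(conv_block_filters = c(16L, 32L, 64L),
                          convs_per_block = 2L,
                          kernel = c(3L, 3L),
                          dropout_rate = 0.25,
                          dense_widths = c(768L, 64L),
                          input_shape = c(128L, 12L, 3L),
                          param_range = c(8e5, 1.05e6)) {
  stopifnot(convs_per_block %in% 2:3, dropout_rate >= 0, dropout_rate < 1,
            length(dense_widths) == 2L, length(input_shape) == 3L)
  structure(list(conv_block_filters = as.integer(conv_block_filters),
                 convs_per_block = as.integer(convs_per_block),
                 kernel = as.integer(kernel),
                 dropout_rate = dropout_rate,
                 dense_widths = as.integer(dense_widths),
                 input_shape = as.integer(input_shape),
                 param_range = param_range),
            class = "detector_spec")
}

#' Training protocol for a detector
#'
#' Defaults follow the reference protocol: 100 epochs, batch size 64, early
#' stopping with patience 10 monitoring precision on the held-out test split,
#' Adam with learning rate 0.01, binary cross-entropy loss, an 80/10/10
#' train/test/final split, and 5-fold cross-validation.
#'
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without precision improvement before
#'   stopping (must be < `epochs`).
#' @param learning_rate Adam learning rate.
#' @param split_fractions train/test/final fractions (sum to 1); precision is
#'   monitored on the test split at `decision_threshold`.
#' @param k_folds folds for [kfold_cv()].
#' @param decision_threshold sigmoid threshold for a positive call.
#' @param class_weighting inverse-frequency sample weighting for the heavily
#'   imbalanced segment labels (off by default).
#' @param seed RNG seed for initialization, splits, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         early_stop_patience = 10L,
                         learning_rate = 0.01,
                         split_fractions = c(0.8, 0.1, 0.1),
                         k_folds = 5L,
                         decision_threshold = 0.5,
                         class_weighting = FALSE,
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split_fractions must sum to 1")
  if (early_stop_patience >= epochs)
    stop("early_stop_patience must be smaller than epochs")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_monitor = "precision",
                 optimizer = "adam", loss = "binary_crossentropy",
                 learning_rate = learning_rate,
                 split_fractions = split_fractions,
                 k_folds = as.integer(k_folds),
                 decision_threshold = decision_threshold,
                 class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter initialization ---------------------------------------------

.he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

.init_params <- function(spec) {
  k <- spec$kernel
  filters <- spec$conv_block_filters
  p <- list(); s <- list()
  cin <- spec$input_shape[3]
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  for (i in seq_along(filters)) {
    co <- filters[i]
    for (j in seq_len(spec$convs_per_block)) {
      fan <- k[1] * k[2] * cin
      p[[sprintf("b%d.W%d", i, j)]] <- .he_init(c(k[1], k[2], cin, co), fan)
      p[[sprintf("b%d.b%d", i, j)]] <- numeric(co)
      cin <- co
    }
    p[[sprintf("b%d.g", i)]] <- rep(1, co)
    p[[sprintf("b%d.be", i)]] <- numeric(co)
    s[[sprintf("b%d.rm", i)]] <- numeric(co)
    s[[sprintf("b%d.rv", i)]] <- rep(1, co)
    h <- h %/% 2L; w <- w %/% 2L
  }
  d_in <- h * w * cin
  d1 <- spec$dense_widths[1]; d2 <- spec$dense_widths[2]
  p[["d1.W"]] <- .he_init(c(d_in, d1), d_in)
  p[["d1.b"]] <- numeric(d1)
  p[["d1.alpha"]] <- rep(0.25, d1)
  p[["d1.g"]] <- rep(1, d1)
  p[["d1.be"]] <- numeric(d1)
  s[["d1.rm"]] <- numeric(d1)
  s[["d1.rv"]] <- rep(1, d1)
  p[["d2.W"]] <- .he_init(c(d1, d2), d1)
  p[["d2.b"]] <- numeric(d2)
  p[["out.W"]] <- .he_init(c(d2, 1L), d2)
  p[["out.b"]] <- 0
  list(params = p, state = s, flat_dim = d_in)
}

#' Number of trainable parameters of a detector
#' @param model a `jump_cnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

#' Build an untrained jump-event detector
#'
#' Initializes the network of `spec` with He-normal weights under `seed`;
#' identical seeds give identical initial models. Errors if the trainable
#' parameter count falls outside `spec$param_range`, guarding against
#' accidental drift from the intended model size.
#'
#' @param spec a [detector_spec()].
#' @param seed integer RNG seed for the initialization.
#' @return An object of class `jump_cnn`.
#' @export
build_detector <- function(spec = detector_spec(), seed = 1L) {
  set.seed(seed)
  init <- .init_params(spec)
  model <- structure(list(spec = spec, params = init$params,
                          state = init$state, flat_dim = init$flat_dim,
                          stand_stats = NULL, target = NULL,
                          trained = FALSE, history = NULL, seed = seed),
                     class = "jump_cnn")
  np <- n_params(model)
  if (np < spec$param_range[1] || np > spec$param_range[2])
    stop("detector has ", np, " trainable parameters, outside the admissible ",
         "range [", spec$param_range[1], ", ", spec$param_range[2], "]")
  model
}

# ---- forward / backward ----------------------------------------------------

.relu <- function(z) { z[z < 0] <- 0; z }

.cnn_forward <- function(model, X, train = FALSE) {
  spec <- model$spec; p <- model$params; st <- model$state
  drop_p <- if (train) spec$dropout_rate else 0
  cache <- list(blocks = vector("list", length(spec$conv_block_filters)))
  A <- X
  for (i in seq_along(spec$conv_block_filters)) {
    bc <- list(cols = list(), in_dim = list(), Y = list())
    for (j in seq_len(spec$convs_per_block)) {
      if (train) bc$in_dim[[j]] <- dim(A)
      cf <- .conv2d_fw_cache(A, p[[sprintf("b%d.W%d", i, j)]],
                             p[[sprintf("b%d.b%d", i, j)]],
                             TRUE, train)
      A <- cf$Y                    # post-ReLU activation
      if (train) { bc$cols[[j]] <- cf$cols; bc$Y[[j]] <- A }
      if (j == 1L) {               # batch norm after the first conv's ReLU
        d <- dim(A)
        m <- d[1] * d[2] * d[4]
        if (train) {
          mu <- .channel_sums_cpp(A, NULL) / m
          va <- .channel_sums_cpp(A, A) / m - mu^2
          st[[sprintf("b%d.rm", i)]] <- .BN_MOMENTUM * st[[sprintf("b%d.rm", i)]] +
            (1 - .BN_MOMENTUM) * mu
          st[[sprintf("b%d.rv", i)]] <- .BN_MOMENTUM * st[[sprintf("b%d.rv", i)]] +
            (1 - .BN_MOMENTUM) * va
        } else {
          mu <- st[[sprintf("b%d.rm", i)]]
          va <- st[[sprintf("b%d.rv", i)]]
        }
        invstd <- 1 / sqrt(va + .BN_EPS)
        gam <- p[[sprintf("b%d.g", i)]]
        sc <- gam * invstd
        sh <- p[[sprintf("b%d.be", i)]] - mu * sc
        if (train) bc$bn <- list(pre = A, mu = mu, invstd = invstd)
        A <- .channel_scale_shift(A, sc, sh)
      }
    }
    if (drop_p > 0) {
      mask <- (stats::runif(length(A)) >= drop_p) / (1 - drop_p)
      dim(mask) <- dim(A)
      A <- A * mask
      bc$drop_mask <- mask
    }
    bc$prepool_dim <- dim(A)
    A <- .avgpool2_fw(A)
    cache$blocks[[i]] <- bc
    cache$pool_out_dim <- dim(A)
  }
  n <- dim(A)[4]
  f <- t(matrix(A, nrow = model$flat_dim, ncol = n))       # N x D
  cache$pool_out <- A
  cache$f <- f
  z1 <- f %*% p[["d1.W"]] + matrix(p[["d1.b"]], n, length(p[["d1.b"]]),
                                   byrow = TRUE)
  cache$z1 <- z1
  alpha <- matrix(p[["d1.alpha"]], n, ncol(z1), byrow = TRUE)
  a1 <- ifelse(z1 > 0, z1, alpha * z1)
  if (drop_p > 0) {
    dmask <- matrix((stats::runif(length(a1)) >= drop_p) / (1 - drop_p),
                    nrow(a1), ncol(a1))
    a1 <- a1 * dmask
    cache$dense_drop_mask <- dmask
  }
  if (train) {
    mu <- colMeans(a1); va <- colMeans(a1^2) - mu^2
    st[["d1.rm"]] <- .BN_MOMENTUM * st[["d1.rm"]] + (1 - .BN_MOMENTUM) * mu
    st[["d1.rv"]] <- .BN_MOMENTUM * st[["d1.rv"]] + (1 - .BN_MOMENTUM) * va
  } else {
    mu <- st[["d1.rm"]]; va <- st[["d1.rv"]]
  }
  invstd <- 1 / sqrt(va + .BN_EPS)
  xhat <- sweep(sweep(a1, 2, mu), 2, invstd, `*`)
  bn1 <- sweep(sweep(xhat, 2, p[["d1.g"]], `*`), 2, p[["d1.be"]], `+`)
  cache$dense_bn <- list(xhat = xhat, invstd = invstd, a1 = a1)
  z2 <- bn1 %*% p[["d2.W"]] + matrix(p[["d2.b"]], n, ncol(p[["d2.W"]]),
                                     byrow = TRUE)
  cache$bn1 <- bn1; cache$z2 <- z2
  logit <- z2 %*% p[["out.W"]] + p[["out.b"]]
  prob <- 1 / (1 + exp(-logit))
  list(prob = as.numeric(prob), logit = as.numeric(logit),
       cache = cache, state = st)
}

.cnn_backward <- function(model, fw, y, weights = NULL) {
  spec <- model$spec; p <- model$params; cache <- fw$cache
  n <- length(y)
  g <- list()
  dlogit <- matrix((fw$prob - y) / n, n, 1L)
  if (!is.null(weights)) dlogit <- dlogit * weights
  g[["out.W"]] <- t(cache$z2) %*% dlogit
  g[["out.b"]] <- sum(dlogit)
  dz2 <- dlogit %*% t(p[["out.W"]])
  g[["d2.W"]] <- t(cache$bn1) %*% dz2
  g[["d2.b"]] <- colSums(dz2)
  dbn1 <- dz2 %*% t(p[["d2.W"]])
  # dense batch-norm backward
  bn <- cache$dense_bn
  g[["d1.g"]] <- colSums(dbn1 * bn$xhat)
  g[["d1.be"]] <- colSums(dbn1)
  dxhat <- sweep(dbn1, 2, p[["d1.g"]], `*`)
  da1 <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE) -
                 bn$xhat * matrix(colMeans(dxhat * bn$xhat), n, ncol(dxhat),
                                  byrow = TRUE),
               2, bn$invstd, `*`)
  if (!is.null(cache$dense_drop_mask)) da1 <- da1 * cache$dense_drop_mask
  z1 <- cache$z1
  neg <- z1 < 0
  g[["d1.alpha"]] <- colSums(ifelse(neg, da1 * z1, 0))
  alpha <- matrix(p[["d1.alpha"]], n, ncol(z1), byrow = TRUE)
  dz1 <- da1 * ifelse(neg, alpha, 1)
  g[["d1.W"]] <- t(cache$f) %*% dz1
  g[["d1.b"]] <- colSums(dz1)
  df <- dz1 %*% t(p[["d1.W"]])
  dA <- array(t(df), dim(cache$pool_out))
  for (i in rev(seq_along(spec$conv_block_filters))) {
    bc <- cache$blocks[[i]]
    dA <- .avgpool2_bw(dA, bc$prepool_dim[1], bc$prepool_dim[2])
    if (!is.null(bc$drop_mask)) dA <- dA * bc$drop_mask
    for (j in rev(seq_len(spec$convs_per_block))) {
      if (j == 1L) {               # undo batch norm (sits after conv 1's ReLU)
        bn <- bc$bn
        bb <- .bn_bw_conv(dA, bn$pre, bn$mu, bn$invstd,
                          model$params[[sprintf("b%d.g", i)]])
        g[[sprintf("b%d.g", i)]] <- bb$dgamma
        g[[sprintf("b%d.be", i)]] <- bb$dbeta
        dA <- bb$dX
      }
      dZ <- .relu_bw(dA, bc$Y[[j]])
      bw <- .conv2d_bw_cache(bc$cols[[j]], bc$in_dim[[j]],
                             model$params[[sprintf("b%d.W%d", i, j)]], dZ)
      g[[sprintf("b%d.W%d", i, j)]] <- bw$dW
      g[[sprintf("b%d.b%d", i, j)]] <- bw$db
      dA <- bw$dX
    }
  }
  g
}

.bce_loss <- function(prob, y, weights = NULL) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (!is.null(weights)) ll <- ll * weights
  mean(ll)
}

.adam_init <- function(params, lr) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L, lr = lr, b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

.adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t; c2 <- 1 - opt$b2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * gr
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * gr^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# ---- prediction ------------------------------------------------------------

#' Predict event probabilities for segments
#'
#' Runs the detector in inference mode (batch-norm running statistics, no
#' dropout). Raw segments are standardized with the statistics stored in the
#' model at training time — never with their own.
#'
#' @param object a `jump_cnn`.
#' @param newdata a `segment_batch` or a bands x frames x 3 x S array.
#' @param type `"prob"` for sigmoid outputs, `"class"` for 0/1 calls at
#'   `threshold`.
#' @param threshold decision threshold for `type = "class"`.
#' @param standardize apply the model's stored channel statistics (set to
#'   `FALSE` if `newdata` is already standardized).
#' @param chunk_size forward-pass batch size.
#' @param ... unused.
#' @return Numeric vector of probabilities (or integer 0/1 calls).
#' @export
predict.jump_cnn <- function(object, newdata, type = c("prob", "class"),
                             threshold = 0.5, standardize = TRUE,
                             chunk_size = 256L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "segment_batch")) {
    if (standardize && !is.null(object$stand_stats))
      newdata <- apply_channel_stats(newdata, object$stand_stats)
    X <- newdata$segments
  } else {
    X <- newdata
    if (standardize && !is.null(object$stand_stats))
      for (ch in 1:3)
        X[, , ch, ] <- (X[, , ch, ] - object$stand_stats$mean[ch]) /
          object$stand_stats$sd[ch]
  }
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  d <- dim(X)
  if (!all(d[1:3] == object$spec$input_shape))
    stop("segment shape ", paste(d[1:3], collapse = "x"),
         " does not match the detector input ",
         paste(object$spec$input_shape, collapse = "x"))
  s <- d[4]
  out <- numeric(s)
  for (i0 in seq(1L, s, by = chunk_size)) {
    i1 <- min(s, i0 + chunk_size - 1L)
    Xi <- X[, , , i0:i1, drop = FALSE]
    out[i0:i1] <- .cnn_forward(object, Xi, train = FALSE)$prob
  }
  if (type == "class") as.integer(out >= threshold) else out
}

# ---- training --------------------------------------------------------------

#' Train a binary jump-event detector
#'
#' Trains on labeled 12-frame segments with binary cross-entropy and Adam.
#' The batch is split into train/test/final portions per
#' `config$split_fractions` (seeded); per-channel standardization statistics
#' are fitted on the training portion and stored in the model. After each
#' epoch, precision on the test portion (at `config$decision_threshold`) is
#' monitored; training stops early when it has not improved for
#' `config$early_stop_patience` epochs, and the best-precision weights are
#' restored (ties broken by recall).
#'
#' @param model an untrained (or warm) `jump_cnn` from [build_detector()].
#' @param batch a labeled `segment_batch` (see [label_segments()]).
#' @param target which event the detector learns: `"landing"` or
#'   `"takeoff"`.
#' @param config a [train_config()].
#' @param quiet suppress per-epoch progress.
#' @return The trained `jump_cnn`, with `history` (per-epoch loss and
#'   monitored metrics) and `final_idx` (indices of the untouched final
#'   evaluation split).
#' @export
train_detector <- function(model, batch, target = c("landing", "takeoff"),
                           config = train_config(), quiet = TRUE) {
  target <- match.arg(target)
  stopifnot(inherits(model, "jump_cnn"), inherits(batch, "segment_batch"))
  y <- if (target == "landing") batch$labels_landing else batch$labels_takeoff
  if (is.null(y)) stop("segment batch is unlabeled; see label_segments()")
  s <- length(y)
  set.seed(config$seed)
  idx <- sample.int(s)
  n_tr <- round(config$split_fractions[1] * s)
  n_te <- round(config$split_fractions[2] * s)
  tr <- idx[seq_len(n_tr)]
  te <- idx[(n_tr + 1):(n_tr + n_te)]
  fin <- idx[-seq_len(n_tr + n_te)]
  if (length(unique(y[tr])) < 2L)
    stop("training split contains a single class; cannot train a binary detector")
  if (is.null(model$stand_stats)) {
    trb <- batch; trb$segments <- batch$segments[, , , tr, drop = FALSE]
    model$stand_stats <- channel_stats(trb)
  }
  batch <- apply_channel_stats(batch, model$stand_stats)
  X <- batch$segments
  w_tr <- NULL
  if (config$class_weighting) {
    tab <- table(factor(y[tr], levels = 0:1))
    w_all <- length(tr) / (2 * pmax(tab, 1L))
    w_tr <- as.numeric(w_all[as.character(y)])
  }
  opt <- .adam_init(model$params, config$learning_rate)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_precision = numeric(), val_recall = numeric())
  best <- list(prec = -Inf, rec = -Inf, params = model$params,
               state = model$state, epoch = 0L)
  wait <- 0L
  Xte <- X[, , , te, drop = FALSE]
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    for (i0 in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[i0:min(length(ord), i0 + config$batch_size - 1L)]
      if (length(bi) < 2L) next     # batch norm needs >= 2 samples
      Xi <- X[, , , bi, drop = FALSE]
      yi <- y[bi]
      wi <- if (is.null(w_tr)) NULL else w_tr[bi]
      fw <- .cnn_forward(model, Xi, train = TRUE)
      model$state <- fw$state
      losses <- c(losses, .bce_loss(fw$prob, yi, wi))
      grads <- .cnn_backward(model, fw, yi,
                             if (is.null(wi)) NULL else matrix(wi, ncol = 1L))
      upd <- .adam_step(model$params, grads, opt)
      model$params <- upd$params
      opt <- upd$opt
    }
    pte <- numeric(0)
    if (length(te))
      pte <- predict(model, Xte, standardize = FALSE)
    calls <- as.integer(pte >= config$decision_threshold)
    met <- classification_metrics(sum(calls == 1 & y[te] == 1),
                                  sum(calls == 1 & y[te] == 0),
                                  sum(calls == 0 & y[te] == 1))
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_precision = met$precision,
                                   val_recall = met$recall))
    if (!quiet)
      message(sprintf("epoch %3d  loss %.4f  val P %.3f R %.3f",
                      epoch, mean(losses), met$precision, met$recall))
    improved <- met$precision > best$prec ||
      (met$precision == best$prec && met$recall > best$rec)
    if (improved) {
      best <- list(prec = met$precision, rec = met$recall,
                   params = model$params, state = model$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$target <- target
  model$history <- hist
  model$best_epoch <- best$epoch
  model$final_idx <- fin
  model$train_config <- config
  model
}

# ---- methods ---------------------------------------------------------------

#' @export
print.jump_cnn <- function(x, ...) {
  cat(sprintf("<jump_cnn> %s detector | blocks %s (x%d convs) | dense %s | %d parameters | %s\n",
              if (is.null(x$target)) "untrained" else x$target,
              paste(x$spec$conv_block_filters, collapse = "/"),
              x$spec$convs_per_block,
              paste(x$spec$dense_widths, collapse = "/"),
              n_params(x),
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' @export
summary.jump_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  epochs run: %d | final loss %.4f | best val precision %.3f (recall %.3f)\n",
                nrow(h), h$loss[nrow(h)],
                max(h$val_precision), h$val_recall[which.max(h$val_precision)]))
  }
  invisible(object)
}

#' @export
coef.jump_cnn <- function(object, ...) object$params

#' @export
plot.jump_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_precision, type = "b", col = "firebrick",
                 ylim = c(0, 1), xlab = "epoch", ylab = "metric",
                 main = "held-out precision/recall")
  graphics::lines(h$epoch, h$val_recall, type = "b", col = "steelblue")
  graphics::legend("bottomright", c("precision", "recall"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a trained detector
#'
#' The model is serialized as RDS next to a JSON sidecar recording the
#' architecture, training protocol, seed, parameter count and
#' standardization statistics for auditability.
#'
#' @param model a `jump_cnn`.
#' @param path output path (`.rds`; the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "jump_cnn"))
  saveRDS(model, path)
  side <- list(class = "jump_cnn", target = model$target,
               trained = model$trained, n_params = n_params(model),
               spec = unclass(model$spec), seed = model$seed,
               train_config = if (!is.null(model$train_config))
                 unclass(model$train_config),
               stand_stats = model$stand_stats)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "jump_cnn"))
  model
}

# ---- metrics ---------------------------------------------------------------

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the
#' conventions `P = 0` when `TP+FP = 0`, `R = 0` when `TP+FN = 0`, and
#' `F1 = 0` when `P+R = 0`.
#'
#' @param tp,fp,fn non-negative counts of true positives, false positives,
#'   false negatives.
#' @return A list with `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' K-fold cross-validation of a detector
#'
#' Folds partition *recordings*, not segments: all segments of a recording —
#' and of its noise-augmented twin, which shares its `base_id` — land in the
#' same fold, so augmentation cannot leak between training and validation.
#' Each fold's held-out segments are scored at `config$decision_threshold`.
#'
#' @param batch a labeled `segment_batch` carrying `base_id` per segment
#'   (see [recording_segments()]).
#' @param target `"landing"` or `"takeoff"`.
#' @param spec a [detector_spec()].
#' @param config a [train_config()]; `config$k_folds` folds are used.
#' @param quiet suppress progress.
#' @return An object of class `cv_metrics`: `folds` (per-fold data.frame of
#'   counts and metrics) and `means` (column means of precision/recall/F1).
#' @export
kfold_cv <- function(batch, target = c("landing", "takeoff"),
                     spec = detector_spec(), config = train_config(),
                     quiet = TRUE) {
  target <- match.arg(target)
  if (is.null(batch$base_id))
    stop("batch must carry base_id per segment; see recording_segments()")
  k <- config$k_folds
  if (k < 2L) stop("k_folds must be at least 2")
  ids <- unique(batch$base_id)
  if (length(ids) < k)
    stop("dataset has ", length(ids), " recordings; need at least ", k,
         " for ", k, "-fold cross-validation")
  set.seed(config$seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold_of) <- ids
  y_all <- if (target == "landing") batch$labels_landing else batch$labels_takeoff
  rows <- NULL
  for (f in seq_len(k)) {
    hold <- batch$base_id %in% ids[fold_of == f]
    trb <- .subset_batch(batch, !hold)
    teb <- .subset_batch(batch, hold)
    model <- build_detector(spec, seed = config$seed + f)
    model <- train_detector(model, trb, target, config, quiet = quiet)
    pr <- predict(model, teb)
    calls <- as.integer(pr >= config$decision_threshold)
    yte <- y_all[hold]
    tp <- sum(calls == 1 & yte == 1)
    fp <- sum(calls == 1 & yte == 0)
    fn <- sum(calls == 0 & yte == 1)
    met <- classification_metrics(tp, fp, fn)
    rows <- rbind(rows, data.frame(fold_index = f, true_positives = tp,
                                   false_positives = fp, false_negatives = fn,
                                   precision = met$precision,
                                   recall = met$recall, f1 = met$f1))
  }
  structure(list(folds = rows,
                 means = colMeans(rows[, c("precision", "recall", "f1")]),
                 fold_assignment = fold_of),
            class = "cv_metrics")
}

.subset_batch <- function(batch, keep) {
  out <- batch
  out$segments <- batch$segments[, , , keep, drop = FALSE]
  out$segment_start_times <- batch$segment_start_times[keep]
  for (nm in c("labels_landing", "labels_takeoff", "recording_id", "base_id"))
    if (!is.null(batch[[nm]])) out[[nm]] <- batch[[nm]][keep]
  out
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat("K-fold cross-validation:\n")
  print(x$folds[, c("fold_index", "precision", "recall", "f1")],
        row.names = FALSE, digits = 3)
  cat(sprintf("Mean  P %.3f  R %.3f  F1 %.3f\n",
              x$means["precision"], x$means["recall"], x$means["f1"]))
  invisible(x)
}

#' Write cross-validation metrics as CSV
#'
#' Columns `K-Fold,Precision,Recall,F1-Score` with one row per fold and a
#' closing `Mean` row of column means.
#'
#' @param cv a `cv_metrics` from [kfold_cv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_metrics <- function(cv, path) {
  df <- data.frame(`K-Fold` = c(as.character(cv$folds$fold_index), "Mean"),
                   Precision = c(cv$folds$precision, cv$means["precision"]),
                   Recall = c(cv$folds$recall, cv$means["recall"]),
                   `F1-Score` = c(cv$folds$f1, cv$means["f1"]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
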