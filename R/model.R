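# Dual-branch fusion classifier: a residual image encoder (initial 7x7 conv,
# 3x3 max-pool, four two-unit residual stages, global average pooling), a
# waveform encoder (five 1-D conv stages with kernel 5 and channels growing
# 16->32->64->128->256, max-pool stride 2 in stages 1-4 so the 64-sample axis
# ends at length 4, then a 4-layer unidirectional LSTM and two FC layers), and
# a three-layer fused classifier head.  Trained with weighted cross-entropy
# (abnormal weight 5, normal weight 1), Adam at constant lr 1e-4, weight decay
# 1e-4, gradient-norm clipping at 1, batch 16, early stopping on validation
# loss.

#' Model configuration
#'
#' Defaults mirror the reference architecture: 224 x 224 image input, a
#' 512-dimensional image feature, waveform conv channels (16, 32, 64, 128,
#' 256), a 4-layer LSTM of hidden size 64, a 64-dimensional waveform feature,
#' and a 576-dimensional fused vector feeding a 576 -> 256 -> 64 -> 2 head.
#'
#' @param image_input_size Image side length after bilinear resize.
#' @param image_stage_widths Residual-stage widths; the image feature length
#'   equals the last width.
#' @param conv_channels Waveform conv-stage channels (strictly increasing).
#' @param conv_kernel Waveform conv kernel size.
#' @param lstm_layers,lstm_hidden LSTM depth and hidden size.
#' @param wave_feature_dim Waveform feature length.
#' @param classifier_widths Hidden widths of the fused classifier.
#' @param dropout Dropout rate in the first classifier layer.
#' @param n_classes Output classes (2).
#' @param n_channels Flattened transmit-receive channel count (144).
#' @param wave_len Truncated waveform length (64).
#' @param use_pretrained_image_backbone Reserved flag; no pretrained weights
#'   ship with the package, so the 1-channel stem is randomly initialized
#'   (default and only supported setting offline).
#' @param seed Weight-initialization seed.
#' @return Object of class `model_config`; `fusion_dim` is derived as
#'   image feature + waveform feature length.
#' @export
model_config <- function(image_input_size = 224L,
                         image_stage_widths = c(64L, 128L, 256L, 512L),
                         conv_channels = c(16L, 32L, 64L, 128L, 256L),
                         conv_kernel = 5L,
                         lstm_layers = 4L, lstm_hidden = 64L,
                         wave_feature_dim = 64L,
                         classifier_widths = c(256L, 64L),
                         dropout = 0.5, n_classes = 2L,
                         n_channels = 144L, wave_len = 64L,
                         use_pretrained_image_backbone = FALSE,
                         seed = 1L) {
  if (any(diff(conv_channels) <= 0))
    stop("conv_channels must be strictly increasing")
  if (length(conv_channels) != 5) stop("five waveform conv stages expected")
  cfg <- list(image_input_size = as.integer(image_input_size),
              image_stage_widths = as.integer(image_stage_widths),
              image_feature_dim = as.integer(tail(image_stage_widths, 1)),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              lstm_layers = as.integer(lstm_layers),
              lstm_hidden = as.integer(lstm_hidden),
              wave_feature_dim = as.integer(wave_feature_dim),
              classifier_widths = as.integer(classifier_widths),
              dropout = dropout, n_classes = as.integer(n_classes),
              n_channels = as.integer(n_channels),
              wave_len = as.integer(wave_len),
              use_pretrained_image_backbone = use_pretrained_image_backbone,
              seed = as.integer(seed))
  cfg$fusion_dim <- cfg$image_feature_dim + cfg$wave_feature_dim
  structure(cfg, class = "model_config")
}

#' Reduced-size configuration for desk-scale experiments
#'
#' Same topology as [model_config()] with smaller widths and a 32 x 32 image
#' input; used by the scaled-down training studies and the test suite.
#'
#' @param seed Weight-initialization seed.
#' @return A `model_config`.
#' @export
model_config_small <- function(seed = 1L) {
  model_config(image_input_size = 32L,
               image_stage_widths = c(8L, 16L, 32L, 64L),
               conv_channels = c(8L, 12L, 16L, 24L, 32L),
               lstm_hidden = 16L, lstm_layers = 2L,
               wave_feature_dim = 16L,
               classifier_widths = c(32L, 16L),
               seed = seed)
}

#' Loss configuration (weighted cross-entropy)
#'
#' @param w0 Weight of the normal class (default 1).
#' @param w1 Weight of the abnormal class (default 5).
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(w0 = 1.0, w1 = 5.0) {
  if (w0 <= 0 || w1 <= 0) stop("class weights must be positive")
  structure(list(w0 = w0, w1 = w1), class = "loss_config")
}

#' Training configuration
#'
#' Defaults mirror the reference protocol: 50 epochs, batch 16, Adam at a
#' constant 1e-4 learning rate, weight decay 1e-4, gradient clipping at 1.0,
#' early stopping on validation loss with patience 10.
#'
#' @param epochs,batch_size,lr,weight_decay,grad_clip,early_stopping_patience
#'   As described.
#' @param seed Seed for shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L, lr = 1e-4,
                         weight_decay = 1e-4, grad_clip = 1.0,
                         early_stopping_patience = 10L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, grad_clip = grad_clip,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- architecture assembly --------------------------------------------------

build_image_branch <- function(cfg) {
  w <- cfg$image_stage_widths
  nn_seq(list(
    nn_conv(1L, w[1], 7L, 7L, 2L, 2L, 3L, 3L, bias = FALSE),
    nn_bn(w[1]), nn_relu(), nn_maxpool(3L, 3L, 2L, 2L, 1L, 1L),
    nn_resblock(w[1], w[1], 1L), nn_resblock(w[1], w[1], 1L),
    nn_resblock(w[1], w[2], 2L), nn_resblock(w[2], w[2], 1L),
    nn_resblock(w[2], w[3], 2L), nn_resblock(w[3], w[3], 1L),
    nn_resblock(w[3], w[4], 2L), nn_resblock(w[4], w[4], 1L),
    nn_gap()))
}

build_wave_pre <- function(cfg) {
  ch <- cfg$conv_channels; k <- cfg$conv_kernel
  prev <- cfg$n_channels
  layers <- list()
  for (s in seq_along(ch)) {
    layers <- c(layers, list(
      nn_conv(prev, ch[s], 1L, k, 1L, 1L, 0L, (k - 1L) %/% 2L),
      nn_bn(ch[s]), nn_relu()))
    if (s < length(ch))  # stages 1-4 downsample; stage 5 keeps length 4
      layers <- c(layers, list(nn_maxpool(1L, 2L, 1L, 2L)))
    prev <- ch[s]
  }
  nn_seq(c(layers, list(nn_squeeze())))
}

build_wave_post <- function(cfg) {
  nn_seq(list(
    nn_lstm(tail(cfg$conv_channels, 1), cfg$lstm_hidden, cfg$lstm_layers),
    nn_take_last(),
    nn_linear(cfg$lstm_hidden, cfg$lstm_hidden), nn_relu(),
    nn_linear(cfg$lstm_hidden, cfg$wave_feature_dim)))
}

build_head <- function(cfg, d_in) {
  cw <- cfg$classifier_widths
  nn_seq(list(
    nn_linear(d_in, cw[1]), nn_relu(), nn_dropout(cfg$dropout),
    nn_linear(cw[1], cw[2]), nn_relu(),
    nn_linear(cw[2], cfg$n_classes)))
}

#' Build a dual-branch (or single-branch ablation) model
#'
#' @param cfg A [model_config()].
#' @param variant One of `"multimodal"`, `"image_only"`, `"wave_only"`.
#' @return Object of class `mw_model` holding the architecture, initialized
#'   parameters and batch-norm state.  Initialization is deterministic in
#'   `cfg$seed`.
#' @export
build_model <- function(cfg, variant = c("multimodal", "image_only", "wave_only")) {
  variant <- match.arg(variant)
  arch <- list()
  d_in <- 0L
  if (variant != "wave_only") {
    arch$img <- build_image_branch(cfg)
    d_in <- d_in + cfg$image_feature_dim
  }
  if (variant != "image_only") {
    arch$wave <- nn_seq(list(build_wave_pre(cfg), build_wave_post(cfg)))
    d_in <- d_in + cfg$wave_feature_dim
  }
  arch$head <- build_head(cfg, d_in)
  with_seed(cfg$seed, {
    params <- lapply(arch, function(a) a$init())
  })
  state <- lapply(arch, function(a) a$state0())
  structure(list(cfg = cfg, variant = variant, arch = arch,
                 params = params, state = state, fused_dim = d_in),
            class = "mw_model")
}

#' @export
print.mw_model <- function(x, ...) {
  cat(sprintf("<mw_model> variant: %s, fused dim: %d, parameters: %d\n",
              x$variant, x$fused_dim, nn_param_count(x$params)))
  invisible(x)
}

# ---- input tensors ----------------------------------------------------------

# separable bilinear interpolation matrix mapping n_in samples to n_out
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    pos <- (o - 0.5) * scale + 0.5   # in input pixel coordinates (1-based)
    i0 <- floor(pos)
    w <- pos - i0
    i0c <- min(max(i0, 1), n_in); i1c <- min(max(i0 + 1, 1), n_in)
    A[o, i0c] <- A[o, i0c] + (1 - w)
    A[o, i1c] <- A[o, i1c] + w
  }
  A
}

#' Bilinear image resize
#'
#' @param img Numeric matrix.
#' @param n_out Output side length.
#' @return `n_out x n_out` matrix.
#' @export
resize_bilinear <- function(img, n_out) {
  A <- bilinear_matrix(nrow(img), n_out)
  B <- bilinear_matrix(ncol(img), n_out)
  A %*% img %*% t(B)
}

# images: list of matrices -> (1, s, s, N); waves: list of L x C matrices ->
# (C, 1, L, N).  No per-sample normalization is applied.
batch_image_tensor <- function(images, s) {
  N <- length(images)
  x <- array(0, c(1L, s, s, N))
  for (n in seq_len(N)) {
    im <- images[[n]]
    if (inherits(im, "confocal_image")) im <- im$I
    if (nrow(im) != s) im <- resize_bilinear(im, s)
    x[1, , , n] <- im
  }
  x
}

batch_wave_tensor <- function(waves, n_channels, L) {
  N <- length(waves)
  x <- array(0, c(n_channels, 1L, L, N))
  for (n in seq_len(N)) x[, 1, , n] <- t(waves[[n]])
  x
}

# ---- forward / loss ---------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

model_forward <- function(model, x_img, x_wave, training = FALSE) {
  caches <- list(); feats <- list()
  state <- model$state
  if (!is.null(model$arch$img)) {
    o <- model$arch$img$fwd(model$params$img, state$img, x_img, training)
    feats$img <- o$y; caches$img <- o$cache; state$img <- o$state
  }
  if (!is.null(model$arch$wave)) {
    o <- model$arch$wave$fwd(model$params$wave, state$wave, x_wave, training)
    feats$wave <- o$y; caches$wave <- o$cache; state$wave <- o$state
  }
  fused <- do.call(rbind, feats)
  o <- model$arch$head$fwd(model$params$head, state$head, fused, training)
  caches$head <- o$cache; state$head <- o$state
  probs <- softmax_cols(o$y)
  list(logits = o$y, probs = probs, feats = feats, caches = caches,
       state = state)
}

model_backward <- function(model, fwd, dlogits) {
  grads <- list()
  o <- model$arch$head$bwd(model$params$head, fwd$caches$head, dlogits)
  grads$head <- o$grads
  dfused <- o$dx
  row0 <- 0L
  if (!is.null(model$arch$img)) {
    d <- nrow(fwd$feats$img)
    oi <- model$arch$img$bwd(model$params$img, fwd$caches$img,
                             dfused[row0 + seq_len(d), , drop = FALSE])
    grads$img <- oi$grads
    row0 <- row0 + d
  }
  if (!is.null(model$arch$wave)) {
    d <- nrow(fwd$feats$wave)
    ow <- model$arch$wave$bwd(model$params$wave, fwd$caches$wave,
                              dfused[row0 + seq_len(d), , drop = FALSE])
    grads$wave <- ow$grads
  }
  grads[names(model$params)]
}

#' Weighted binary cross-entropy
#'
#' \deqn{L = -\frac{1}{N} \sum_i w_1 y_i \log p_i + w_0 (1-y_i) \log(1-p_i)}
#' with `p_i` the predicted abnormal probability (clamped to `[1e-7, 1-1e-7]`
#' for numeric safety) and batch-mean reduction.
#'
#' @param probs Either a `2 x N` class-probability matrix (row 2 = abnormal)
#'   or a numeric vector of abnormal probabilities.
#' @param labels 0/1 vector.
#' @param loss_cfg A [loss_config()].
#' @return Scalar loss.
#' @export
weighted_ce <- function(probs, labels, loss_cfg = loss_config()) {
  p <- if (is.matrix(probs)) probs[2, ] else probs
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  y <- as.numeric(labels)
  mean(-(loss_cfg$w1 * y * log(p) + loss_cfg$w0 * (1 - y) * log(1 - p)))
}

# gradient of weighted_ce w.r.t. the 2-class logits; returns 2 x N matrix
weighted_ce_grad <- function(probs, labels, loss_cfg) {
  p <- pmin(pmax(probs[2, ], 1e-7), 1 - 1e-7)
  y <- as.numeric(labels)
  n <- length(y)
  dz2 <- (-loss_cfg$w1 * y * (1 - p) + loss_cfg$w0 * (1 - y) * p) / n
  rbind(-dz2, dz2)
}

# ---- spec-level encoder operations (inference mode) -------------------------

#' Encode confocal images to feature vectors
#'
#' Bilinear-resizes to the configured input size and runs the residual image
#' branch with global average pooling in inference mode.
#'
#' @param model An `mw_model` containing an image branch.
#' @param images List of [confocal_image()]s or plain matrices.
#' @return `(image_feature_dim x N)` feature matrix.
#' @export
image_encode <- function(model, images) {
  if (is.null(model$arch$img)) stop("model has no image branch")
  x <- batch_image_tensor(images, model$cfg$image_input_size)
  model$arch$img$fwd(model$params$img, model$state$img, x, FALSE)$y
}

#' Encode waveform matrices to feature vectors
#'
#' @param model An `mw_model` containing a waveform branch.
#' @param waves List of `wave_len x n_channels` matrices.
#' @return `(wave_feature_dim x N)` feature matrix.
#' @export
waveform_encode <- function(model, waves) {
  if (is.null(model$arch$wave)) stop("model has no waveform branch")
  x <- batch_wave_tensor(waves, model$cfg$n_channels, model$cfg$wave_len)
  model$arch$wave$fwd(model$params$wave, model$state$wave, x, FALSE)$y
}

#' Waveform conv-stack features (before the LSTM)
#'
#' @param model An `mw_model` containing a waveform branch.
#' @param waves List of waveform matrices.
#' @return `(channels, time_steps, N)` array; `(256, 4, N)` at defaults.
#' @export
wave_conv_features <- function(model, waves) {
  x <- batch_wave_tensor(waves, model$cfg$n_channels, model$cfg$wave_len)
  pre <- model$arch$wave$layers[[1]]
  pre$fwd(model$params$wave[[1]], model$state$wave[[1]], x, FALSE)$y
}

#' Fuse features and classify
#'
#' Concatenates the image feature (first) and waveform feature and applies the
#' three-layer classifier head with softmax output.
#'
#' @param model An `mw_model`.
#' @param f_img,f_wave Feature matrices (either may be `NULL` for ablation
#'   variants).
#' @return `2 x N` probability matrix (columns sum to 1).
#' @export
fuse_classify <- function(model, f_img = NULL, f_wave = NULL) {
  fused <- rbind(f_img, f_wave)
  if (nrow(fused) != model$fused_dim)
    stop(sprintf("fused dimension %d does not match model (%d)",
                 nrow(fused), model$fused_dim))
  z <- model$arch$head$fwd(model$params$head, model$state$head, fused, FALSE)$y
  softmax_cols(z)
}

# ---- training ---------------------------------------------------------------

prepare_inputs <- function(model, samples) {
  cfg <- model$cfg
  imgs <- NULL; waves <- NULL
  if (!is.null(model$arch$img))
    imgs <- batch_image_tensor(lapply(samples, `[[`, "image"),
                               cfg$image_input_size)
  if (!is.null(model$arch$wave))
    waves <- batch_wave_tensor(lapply(samples, `[[`, "wave_matrix"),
                               cfg$n_channels, cfg$wave_len)
  list(img = imgs, wave = waves,
       labels = vapply(samples, `[[`, integer(1), "label2"))
}

slice_inputs <- function(inputs, idx) {
  list(img = if (!is.null(inputs$img)) inputs$img[, , , idx, drop = FALSE],
       wave = if (!is.null(inputs$wave)) inputs$wave[, , , idx, drop = FALSE],
       labels = inputs$labels[idx])
}

eval_loss <- function(model, inputs, loss_cfg, batch_size = 64L) {
  n <- length(inputs$labels)
  tot <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- slice_inputs(inputs, idx)
    fwd <- model_forward(model, b$img, b$wave, training = FALSE)
    tot <- tot + weighted_ce(fwd$probs, b$labels, loss_cfg) * length(idx)
  }
  tot / n
}

#' Train a model
#'
#' Mini-batch Adam with constant learning rate, weight decay, global
#' gradient-norm clipping, dropout, and early stopping on validation loss.
#' Deterministic given the configuration seeds under single-threaded
#' execution.  Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model An untrained `mw_model` from [build_model()].
#' @param samples List of [sample_record()]s.
#' @param split A [split_dataset()] `split_spec`.
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param verbose Print per-epoch losses.
#' @return The model with trained parameters and a `log` data frame of
#'   per-epoch train/validation losses (and the grad-norm of the last batch).
#' @export
train_model <- function(model, samples, split, train_cfg = train_config(),
                        loss_cfg = loss_config(), verbose = FALSE) {
  inputs_tr <- prepare_inputs(model, samples[split$train_ids])
  inputs_val <- prepare_inputs(model, samples[split$val_ids])
  n_tr <- length(inputs_tr$labels)
  opt <- adam_init(model$params)
  best <- list(val = Inf, params = model$params, state = model$state, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  patience_left <- train_cfg$early_stopping_patience
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      for (start in seq(1, n_tr, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1, n_tr)]
        b <- slice_inputs(inputs_tr, idx)
        fwd <- model_forward(model, b$img, b$wave, training = TRUE)
        model$state <- fwd$state
        loss <- weighted_ce(fwd$probs, b$labels, loss_cfg)
        if (!is.finite(loss))
          stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        ep_loss <- ep_loss + loss * length(idx)
        dz <- weighted_ce_grad(fwd$probs, b$labels, loss_cfg)
        grads <- model_backward(model, fwd, dz)
        grads <- clip_grads(grads, train_cfg$grad_clip)
        step <- adam_step(model$params, grads, opt, train_cfg$lr,
                          weight_decay = train_cfg$weight_decay)
        model$params <- step$params; opt <- step$opt
      }
      val <- eval_loss(model, inputs_val, loss_cfg)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n_tr,
                                   val_loss = val))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / n_tr, val))
      if (val < best$val - 1e-9) {
        best <- list(val = val, params = model$params, state = model$state,
                     epoch = epoch)
        patience_left <- train_cfg$early_stopping_patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  model$log <- log
  model$best_epoch <- best$epoch
  model
}

#' Predict abnormal-class probabilities
#'
#' @param model A trained `mw_model`.
#' @param samples List of [sample_record()]s.
#' @param batch_size Evaluation batch size.
#' @return A [prediction_set()] with scores, labels and sample ids.
#' @export
predict_model <- function(model, samples, batch_size = 64L) {
  inputs <- prepare_inputs(model, samples)
  n <- length(inputs$labels)
  scores <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- slice_inputs(inputs, idx)
    fwd <- model_forward(model, b$img, b$wave, training = FALSE)
    scores[idx] <- fwd$probs[2, ]
  }
  prediction_set(scores, inputs$labels,
                 ids = vapply(samples, function(s)
                   as.character(s$sample_id), character(1)))
}

#' Modality ablation study
#'
#' Trains the multimodal, image-only and waveform-only variants with the
#' identical split and training protocol, evaluates each on the byte-identical
#' test split, and keeps paired predictions for significance testing.
#'
#' @param samples List of [sample_record()]s.
#' @param split A `split_spec` shared across variants.
#' @param cfg A [model_config()].
#' @param train_cfg,loss_cfg Training and loss configurations.
#' @param variants Variants to run.
#' @param verbose Print progress.
#' @return Named list per variant: `model`, `preds` (test-set
#'   [prediction_set()]), `report` (a [metric_report()]).
#' @export
ablate <- function(samples, split, cfg = model_config_small(),
                   train_cfg = train_config(), loss_cfg = loss_config(),
                   variants = c("multimodal", "image_only", "wave_only"),
                   verbose = FALSE) {
  out <- list()
  for (v in variants) {
    if (verbose) message("training variant: ", v)
    m <- build_model(cfg, v)
    m <- train_model(m, samples, split, train_cfg, loss_cfg, verbose = verbose)
    preds <- predict_model(m, samples[split$test_ids])
    out[[v]] <- list(model = m, preds = preds,
                     report = metric_report(preds, seed = train_cfg$seed))
  }
  out
}
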