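# SheepVGG-Lite: a shallow VGG-style CNN used as a deep-feature extractor
# for 100 x 100 x 3 spectrogram images. Two conv(3x3, pad 1) + ReLU +
# maxpool(2x2) blocks (3 -> 16 -> 32 channels) feed a 20,000-wide flatten,
# a 128-unit fully connected layer (FC1) and a 3-class logit layer (FC2).
# Convolution/pooling kernels live in src/conv_ops.cpp; Adam, the epoch
# loop and checkpointing live here. Weights are held at 32-bit float
# precision so a serialized model reloads to bit-identical logits.

SVGG_H <- 100L
SVGG_C1 <- 16L
SVGG_C2 <- 32L
SVGG_FLAT <- 20000L   # 25 * 25 * 32
SVGG_FC1 <- 128L
SVGG_NCLASS <- 3L

# Round a numeric vector to its nearest 32-bit float representation.
quantize_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), numeric(),
          n = length(x), size = 4L)
}

quantize_params <- function(params) {
  lapply(params, function(p) {
    q <- quantize_f32(p)
    if (is.matrix(p)) dim(q) <- dim(p)
    q
  })
}

#' Build an initialized SheepVGG-Lite model
#'
#' Seeded He-normal weight initialization; biases start at zero. The
#' trainable parameter count is 2,565,603
#' (448 + 4,640 + 2,560,128 + 387).
#'
#' @param seed Initialization seed.
#' @return An object of class `"sheepvgg"`.
#' @export
sheepvgg_lite <- function(seed = 1L) {
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(27 * SVGG_C1, sd = sqrt(2 / 27)), 27, SVGG_C1),
    b1 = numeric(SVGG_C1),
    W2 = matrix(rnorm(9 * SVGG_C1 * SVGG_C2, sd = sqrt(2 / (9 * SVGG_C1))),
                9 * SVGG_C1, SVGG_C2),
    b2 = numeric(SVGG_C2),
    W3 = matrix(rnorm(SVGG_FLAT * SVGG_FC1, sd = sqrt(2 / SVGG_FLAT)),
                SVGG_FLAT, SVGG_FC1),
    b3 = numeric(SVGG_FC1),
    W4 = matrix(rnorm(SVGG_FC1 * SVGG_NCLASS, sd = sqrt(2 / SVGG_FC1)),
                SVGG_FC1, SVGG_NCLASS),
    b4 = numeric(SVGG_NCLASS)))
  structure(list(params = quantize_params(params), classes = NULL,
                 seed = as.integer(seed), trained = FALSE, history = NULL,
                 config = NULL, best_epoch = NA_integer_),
            class = "sheepvgg")
}

#' Number of trainable parameters
#'
#' @param model A `"sheepvgg"` model.
#' @return Integer parameter count (2,565,603 for the pinned
#'   architecture).
#' @export
sheepvgg_param_count <- function(model = sheepvgg_lite()) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.sheepvgg <- function(x, ...) {
  cat("SheepVGG-Lite: 100x100x3 -> 50x50x16 -> 25x25x32 -> 20000 -> 128 -> 3\n")
  cat(sprintf("  %s parameters (32-bit float), %s\n",
              format(sheepvgg_param_count(x), big.mark = ","),
              if (x$trained) {
                sprintf("trained (%d epochs, best epoch %d, classes: %s)",
                        nrow(x$history), x$best_epoch,
                        paste(x$classes, collapse = ", "))
              } else "untrained"))
  invisible(x)
}

#' Training configuration for SheepVGG-Lite
#'
#' Adam (beta 0.9/0.999), cross-entropy loss, batches of 32, up to 50
#' epochs, and a learning rate interpolated linearly per epoch from 0.001
#' at epoch 1 to 0.0001 at the final epoch. A stratified 25% of the
#' training data is held out as a validation set; the returned weights
#' are the checkpoint with the best validation weighted F1.
#'
#' @param epochs,batch_size,lr_start,lr_end,val_fraction,seed Scalars as
#'   described above.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, lr_start = 1e-3,
                         lr_end = 1e-4, val_fraction = 0.25, seed = 1L) {
  stopifnot(is_count(epochs), is_count(batch_size), lr_start > 0,
            lr_end > 0, val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Per-epoch learning rate of the linear schedule
#'
#' `lr(e) = lr_start + (e - 1)/(epochs - 1) * (lr_end - lr_start)`;
#' 0.001 at epoch 1 and 0.0001 at epoch 50 under the defaults.
#'
#' @param epoch Epoch number (1-based), vectorized.
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (config$epochs == 1L) return(rep(config$lr_start, length(epoch)))
  config$lr_start + (epoch - 1) / (config$epochs - 1) *
    (config$lr_end - config$lr_start)
}

images_to_matrix <- function(images) {
  if (is.matrix(images)) {
    stopifnot(ncol(images) == SVGG_H * SVGG_H * 3L)
    return(images)
  }
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  X <- t(vapply(images, function(im) {
    stopifnot(identical(dim(im)[1:3], c(SVGG_H, SVGG_H, 3L)))
    as.numeric(im)
  }, numeric(SVGG_H * SVGG_H * 3L)))
  X
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Full forward pass; returns intermediates needed by backprop and the
# deep-feature taps. Convolutional stages use the one-image-per-column
# layout of src/conv_ops.cpp; the fully connected stages keep the
# conventional one-row-per-image orientation.
svgg_forward <- function(params, X) {
  xt <- t(X)
  c1 <- cpp_conv_forward(xt, SVGG_H, SVGG_H, 3L, params$W1, params$b1)
  a1 <- relu(c1)
  p1 <- cpp_maxpool_forward(a1, SVGG_H, SVGG_H, SVGG_C1)
  c2 <- cpp_conv_forward(p1$out, 50L, 50L, SVGG_C1, params$W2, params$b2)
  a2 <- relu(c2)
  p2 <- cpp_maxpool_forward(a2, 50L, 50L, SVGG_C2)
  z3 <- sweep(crossprod(p2$out, params$W3), 2, params$b3, `+`)
  fc1 <- relu(z3)
  logits <- sweep(fc1 %*% params$W4, 2, params$b4, `+`)
  list(xt = xt, c1 = c1, p1 = p1, c2 = c2, p2 = p2, z3 = z3, fc1 = fc1,
       logits = logits)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

ce_loss <- function(logits, y_idx) {
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

svgg_backward <- function(params, fwd, y_idx) {
  n <- nrow(fwd$logits)
  p <- softmax_rows(fwd$logits)
  dz4 <- p
  dz4[cbind(seq_len(n), y_idx)] <- dz4[cbind(seq_len(n), y_idx)] - 1
  dz4 <- dz4 / n
  g <- list()
  g$W4 <- crossprod(fwd$fc1, dz4)
  g$b4 <- colSums(dz4)
  dfc1 <- dz4 %*% t(params$W4)
  dz3 <- dfc1 * (fwd$z3 > 0)
  g$W3 <- fwd$p2$out %*% dz3
  g$b3 <- colSums(dz3)
  dp2 <- params$W3 %*% t(dz3)
  da2 <- cpp_maxpool_backward(dp2, fwd$p2$argmax, 50L * 50L * SVGG_C2)
  dc2 <- da2 * (fwd$c2 > 0)
  bw2 <- cpp_conv_backward(fwd$p1$out, dc2, 50L, 50L, SVGG_C1, params$W2,
                           TRUE)
  g$W2 <- bw2$dW
  g$b2 <- bw2$db
  da1 <- cpp_maxpool_backward(bw2$dX, fwd$p1$argmax,
                              SVGG_H * SVGG_H * SVGG_C1)
  dc1 <- da1 * (fwd$c1 > 0)
  bw1 <- cpp_conv_backward(fwd$xt, dc1, SVGG_H, SVGG_H, 3L, params$W1,
                           FALSE)
  g$W1 <- bw1$dW
  g$b1 <- bw1$db
  g[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
}

# Stratified holdout by largest-remainder allocation: per-class quotas
# fraction * n_c are floored, then the remaining slots (to reach
# round(fraction * n)) go to the classes with the largest remainders
# (ties resolved in class order). Shared by the train/test split and the
# training-time validation split.
stratified_holdout <- function(y, fraction, seed) {
  y <- as.character(y)
  classes <- sort(unique(y))
  n_c <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  quota <- fraction * n_c
  take <- floor(quota)
  deficit <- round(fraction * length(y)) - sum(take)
  if (deficit > 0) {
    ord <- order(-(quota - take), seq_along(classes))
    take[ord[seq_len(deficit)]] <- take[ord[seq_len(deficit)]] + 1
  }
  take <- pmin(take, n_c - 1)  # never empty a class's main part
  held <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    idx <- with_seed(child_seed(seed, ci), sample(idx))
    held <- c(held, idx[seq_len(take[ci])])
  }
  list(main = sort(setdiff(seq_along(y), held)), held = sort(held))
}

#' Train SheepVGG-Lite on labelled spectrogram images
#'
#' Runs the training schedule of [train_config()]: seeded stratified
#' validation holdout, per-epoch shuffling, Adam updates at the linearly
#' scheduled learning rate, and per-epoch history (train loss, validation
#' loss, validation weighted F1). The returned model carries the
#' checkpoint with the best validation weighted F1 (earliest epoch on
#' ties), with weights at 32-bit float precision.
#'
#' @param model An untrained (or pre-trained) `"sheepvgg"`.
#' @param images List of 100 x 100 x 3 arrays in `[0, 1]` (e.g. from
#'   [spectrogram_image()]), or an `n x 30000` matrix of flattened images.
#' @param labels Class labels, one per image; at least two classes.
#' @param config A [train_config()].
#' @return The trained `"sheepvgg"` with `history` (one row per epoch),
#'   `classes`, and `best_epoch`.
#' @export
train_sheepvgg <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "sheepvgg"), inherits(config, "train_config"))
  X <- images_to_matrix(images)
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop_foldear("need at least 2 classes to train", "foldear_bad_labels")
  }
  split <- stratified_holdout(y, config$val_fraction, child_seed(config$seed, 1))
  tr <- split$main
  va <- split$held
  if (!setequal(unique(y[va]), classes)) {
    stop_foldear("a class is absent from the validation split",
                 "foldear_bad_split")
  }
  y_idx <- match(y, classes)
  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_f1 <- -Inf
  best_epoch <- NA_integer_
  best_params <- NULL
  history <- data.frame(epoch = seq_len(config$epochs), lr = NA_real_,
                        train_loss = NA_real_, val_loss = NA_real_,
                        val_f1 = NA_real_)
  for (e in seq_len(config$epochs)) {
    lr <- lr_schedule(e, config)
    order_tr <- with_seed(child_seed(config$seed, 100L + e),
                          sample(length(tr)))
    idx_epoch <- tr[order_tr]
    losses <- numeric(0)
    sizes <- numeric(0)
    for (b in seq_len(ceiling(length(idx_epoch) / config$batch_size))) {
      bi <- idx_epoch[(((b - 1L) * config$batch_size + 1L)):
                        min(b * config$batch_size, length(idx_epoch))]
      Xb <- X[bi, , drop = FALSE]
      fwd <- svgg_forward(params, Xb)
      losses <- c(losses, ce_loss(fwd$logits, y_idx[bi]))
      sizes <- c(sizes, length(bi))
      grads <- svgg_backward(params, fwd, y_idx[bi])
      step <- step + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_fwd <- svgg_forward(params, X[va, , drop = FALSE])
    val_loss <- ce_loss(val_fwd$logits, y_idx[va])
    val_pred <- classes[max.col(val_fwd$logits, ties.method = "first")]
    val_f1 <- weighted_f1(val_pred, y[va], classes)
    history[e, -1] <- c(lr, sum(losses * sizes) / sum(sizes), val_loss,
                        val_f1)
    if (val_f1 > best_f1) {
      best_f1 <- val_f1
      best_epoch <- e
      best_params <- quantize_params(params)
    }
  }
  model$params <- best_params
  model$classes <- classes
  model$trained <- TRUE
  model$history <- history
  model$config <- config
  model$best_epoch <- best_epoch
  model
}

#' Predict behavior classes (or logits) for images
#'
#' @param object A trained `"sheepvgg"`.
#' @param images As in [train_sheepvgg()].
#' @param type `"class"` (default), `"logits"` or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes, or an `n x 3` matrix.
#' @export
predict.sheepvgg <- function(object, images, type = c("class", "logits",
                                                      "prob"), ...) {
  type <- match.arg(type)
  X <- images_to_matrix(images)
  logits <- svgg_forward(object$params, X)$logits
  colnames(logits) <- object$classes
  switch(type,
         logits = logits,
         prob = softmax_rows(logits),
         class = {
           if (is.null(object$classes)) {
             stop_foldear("model has no class labels; train it first",
                          "foldear_untrained")
           }
           object$classes[max.col(logits, ties.method = "first")]
         })
}

#' Extract deep features from a fully connected layer
#'
#' Deterministic evaluation-mode forward pass returning the FC1 tap
#' (post-ReLU, 128 columns) or the FC2 tap (pre-softmax class logits,
#' 3 columns) for each image.
#'
#' @param model A trained `"sheepvgg"`.
#' @param images As in [train_sheepvgg()].
#' @param layer `"FC1"` or `"FC2"`.
#' @return `n x 128` or `n x 3` numeric matrix.
#' @export
extract_deep_features <- function(model, images, layer = "FC1") {
  if (!layer %in% c("FC1", "FC2")) {
    stop_foldear(sprintf("unknown layer '%s'; valid taps: FC1, FC2", layer),
                 "foldear_bad_layer")
  }
  fwd <- svgg_forward(model$params, images_to_matrix(images))
  if (layer == "FC1") fwd$fc1 else fwd$logits
}

#' EigenCAM activation heatmap
#'
#' Projects the last convolutional block's post-ReLU activations
#' (25 x 25 x 32 after pooling) onto their first right singular vector
#' (sign chosen so the projected map's maximum is positive), clamps
#' negatives to zero, bilinearly upsamples to 100 x 100 and min-max
#' normalizes to `[0, 1]`. All-zero activations give an all-zero map.
#'
#' @param model A trained `"sheepvgg"`.
#' @param image A single 100 x 100 x 3 image.
#' @return `100 x 100` matrix in `[0, 1]` of class
#'   `"activation_heatmap"`.
#' @export
eigencam <- function(model, image) {
  fwd <- svgg_forward(model$params, images_to_matrix(image))
  A <- matrix(fwd$p2$out[, 1], 625L, SVGG_C2)
  heatmap_from_activations(A)
}

# Core EigenCAM projection from a (spatial x channel) activation matrix.
heatmap_from_activations <- function(A, side = 25L, out_side = 100L) {
  if (all(A == 0)) {
    return(structure(matrix(0, out_side, out_side),
                     class = "activation_heatmap"))
  }
  v <- svd(A, nu = 0, nv = 1)$v[, 1]
  proj <- as.numeric(A %*% v)
  if (max(proj) <= 0) proj <- -proj
  m <- pmax(matrix(proj, side, side), 0)
  up <- bilinear_resize(m, out_side, out_side)
  mx <- max(up)
  mn <- min(up)
  out <- if (mx == 0) up else if (mx > mn) (up - mn) / (mx - mn) else
    up / mx
  structure(out, class = "activation_heatmap")
}

#' Serialize / load a SheepVGG-Lite model
#'
#' Single-file binary format: an 8-byte magic string, a little-endian
#' int32 header length, a JSON header (architecture, classes, seed,
#' training config, best epoch), then the raw 32-bit little-endian
#' parameters in declaration order (W1, b1, W2, b2, W3, b3, W4, b4).
#' Because weights are held at float32 precision, a reloaded model
#' produces bit-identical logits and repeated saves are byte-identical.
#'
#' @param model A `"sheepvgg"`.
#' @param path File path.
#' @return `save_sheepvgg`: `path` invisibly; `load_sheepvgg`: the model.
#' @export
save_sheepvgg <- function(model, path) {
  hdr <- list(format = "sheepvgg-lite", version = 1L,
              input = c(SVGG_H, SVGG_H, 3L),
              channels = c(SVGG_C1, SVGG_C2),
              fc = c(SVGG_FC1, SVGG_NCLASS),
              classes = model$classes, seed = model$seed,
              trained = model$trained, best_epoch = model$best_epoch,
              config = unclass(model$config))
  hraw <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("SVGGL001", con, eos = NULL)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    writeBin(as.numeric(model$params[[nm]]), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' @rdname save_sheepvgg
#' @export
load_sheepvgg <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, "SVGGL001")) {
    stop_foldear("not a sheepvgg model file", "foldear_bad_model_file")
  }
  hlen <- readBin(con, integer(), size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), n = hlen)))
  shapes <- list(W1 = c(27L, SVGG_C1), b1 = SVGG_C1,
                 W2 = c(9L * SVGG_C1, SVGG_C2), b2 = SVGG_C2,
                 W3 = c(SVGG_FLAT, SVGG_FC1), b3 = SVGG_FC1,
                 W4 = c(SVGG_FC1, SVGG_NCLASS), b4 = SVGG_NCLASS)
  params <- lapply(shapes, function(s) {
    v <- readBin(con, numeric(), n = prod(s), size = 4L, endian = "little")
    if (length(s) == 2L) dim(v) <- s
    v
  })
  cfg <- if (!is.null(hdr$config) && length(hdr$config)) {
    do.call(train_config, hdr$config)
  } else NULL
  structure(list(params = params, classes = hdr$classes,
                 seed = hdr$seed %||% NA_integer_,
                 trained = isTRUE(hdr$trained), history = NULL,
                 config = cfg,
                 best_epoch = hdr$best_epoch %||% NA_integer_),
            class = "sheepvgg")
}
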