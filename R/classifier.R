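# ---------------------------------------------------------------------------
# CNN BI-RADS classifier over binary dense-tissue masks: three convolution
# layers (9x9, 5x5, 4x4) with 4x4/stride-4 max-pooling after the first two,
# a 128-unit fully connected layer with dropout 0.5, and a 4-way softmax
# trained with class-weighted cross-entropy under RMSProp.
# ---------------------------------------------------------------------------

#' Configuration of the mask classifier CNN
#'
#' @param input_size mask side length, 64 or 128.
#' @param channels feature maps of the three convolution layers.
#' @param fc1_units width of the first fully connected layer (default 128).
#' @param dropout dropout rate on the first FC layer (default 0.5).
#' @param learning_rate RMSProp learning rate (default 0.001).
#' @param momentum RMSProp momentum (default 0.9).
#' @param batch_size images per batch (default 16).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is halved (reduce-on-plateau schedule).
#' @param class_weights optional 4 weights; computed from the class counts
#'   via [class_weights()] when `NULL`.
#' @param seed integer seed.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 64L, channels = c(16L, 32L, 64L),
                       fc1_units = 128L, dropout = 0.5,
                       learning_rate = 1e-3, momentum = 0.9,
                       batch_size = 16L, epochs = 50L, patience = 15L,
                       lr_patience = 4L, class_weights = NULL, seed = 1L) {
  if (!input_size %in% c(64L, 128L))
    stop("input_size must be 64 or 128")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 fc1_units = as.integer(fc1_units), dropout = dropout,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 lr_patience = as.integer(lr_patience),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "cnn_config")
}

birads_levels <- c("I", "II", "III", "IV")

build_cnn <- function(cfg) {
  ch <- cfg$channels
  # spatial bookkeeping: conv1 same-pad, pool 4/4, conv2 same-pad, pool 4/4,
  # conv3 (4x4, pad 1) shrinks by one; FC1 input computed from input_size.
  s <- cfg$input_size %/% 4L %/% 4L - 1L
  flat <- s * s * ch[3]
  nn_sequential(
    layer_conv(1L, ch[1], 9L, 1L, 4L), layer_act("relu"),
    layer_maxpool(4L, 4L),
    layer_conv(ch[1], ch[2], 5L, 1L, 2L), layer_act("relu"),
    layer_maxpool(4L, 4L),
    layer_conv(ch[2], ch[3], 4L, 1L, 1L), layer_act("relu"),
    layer_flatten(),
    layer_dense(flat, cfg$fc1_units), layer_act("relu"),
    layer_dropout(cfg$dropout),
    layer_dense(cfg$fc1_units, 4L))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), `-`)
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), `/`)
}

#' Train the CNN mask classifier
#'
#' Weighted categorical cross-entropy (`w_c = 1 - n_c/N` by default) under
#' RMSProp, trained from random initialization.  Masks are resized to the
#' configured input size with nearest-neighbour interpolation so they stay
#' binary.  When a validation set is supplied, training stops early after
#' `patience` epochs without validation-loss improvement and the best
#' parameters are restored.
#'
#' @param masks list of binary masks.
#' @param labels BI-RADS labels (`"I".."IV"`), one per mask.
#' @param cfg a [cnn_config()].
#' @param val_masks,val_labels optional validation data.
#' @param verbose print per-epoch progress.
#' @return list of class `cnn_classifier` with `net`, `cfg`, `log`.
#' @export
train_classifier <- function(masks, labels, cfg = cnn_config(),
                             val_masks = NULL, val_labels = NULL,
                             verbose = FALSE) {
  stopifnot(length(masks) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% birads_levels))
    stop("labels must be BI-RADS I..IV")
  for (m in masks) if (!is_binary_mask(m)) stop("masks must be binary (0/1)")

  sz <- cfg$input_size
  prep <- function(ms) lapply(ms, function(m) resize_mask(m, c(sz, sz)))
  xs <- prep(masks)
  y <- match(labels, birads_levels)
  w <- cfg$class_weights
  if (is.null(w)) w <- class_weights(tabulate(y, 4L))
  stopifnot(length(w) == 4L)

  net <- with_seed(stage_seed(cfg$seed, "cnn-init"), build_cnn(cfg))
  opt <- opt_rmsprop(net, lr = cfg$learning_rate, momentum = cfg$momentum)
  pl <- collect_param_layers(net)
  n <- length(xs); B <- cfg$batch_size

  make_tensor <- function(lst, idx) {
    out <- array(0, c(sz, sz, 1L, length(idx)))
    for (j in seq_along(idx)) out[, , 1L, j] <- lst[[idx[j]]]
    out
  }
  eval_set <- NULL
  if (!is.null(val_masks) && length(val_masks) > 0) {
    eval_set <- list(x = prep(val_masks),
                     y = match(as.character(val_labels), birads_levels))
  }
  weighted_ce <- function(p, yi) {
    -mean(w[yi] * log(pmax(p[cbind(yi, seq_along(yi))], 1e-12)))
  }

  best <- list(loss = Inf, params = NULL, since = 0L)
  log_rows <- list()
  with_seed(stage_seed(cfg$seed, "cnn-shuffle"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / B)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * B + 1L):min(bi * B, n)]
        x <- make_tensor(xs, idx)
        yi <- y[idx]
        zero_grads(pl)
        logits <- net$forward(x, train = TRUE)
        p <- softmax_cols(logits)
        ep_loss <- ep_loss + weighted_ce(p, yi)
        onehot <- matrix(0, 4L, length(yi))
        onehot[cbind(yi, seq_along(yi))] <- 1
        dlogits <- sweep(p - onehot, 2, w[yi], `*`) / length(yi)
        net$backward(dlogits, need_dx = FALSE)
        opt$step()
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(eval_set)) {
        lv <- net$forward(make_tensor(eval_set$x, seq_along(eval_set$x)),
                          train = FALSE)
        pv <- softmax_cols(lv)
        val_loss <- weighted_ce(pv, eval_set$y)
        val_acc <- mean(apply(pv, 2, which.max) == eval_set$y)
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = get_params(net), since = 0L)
        } else {
          best$since <- best$since + 1L
          # reduce-on-plateau: halve the rate while validation stalls
          if (best$since %% cfg$lr_patience == 0L)
            opt$lr <- max(opt$lr / 2, 1e-5)
        }
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss, val_acc = val_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss=%.4f  val=%.4f  acc=%s", ep,
                        ep_loss / nb, val_loss,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      if (!is.null(eval_set) && best$since >= cfg$patience) break
    }
  })
  if (!is.null(best$params)) set_params(net, best$params)
  structure(list(net = net, cfg = cfg, class_weights = w,
                 log = do.call(rbind, log_rows)),
            class = "cnn_classifier")
}

#' Classify a binary mask into a BI-RADS category
#'
#' Resizes the mask (nearest-neighbour) to the classifier input size, runs
#' the network in evaluation mode (dropout off) and applies the softmax.
#' Ties resolve to the lowest class index.
#'
#' @param classifier a `cnn_classifier` from [train_classifier()].
#' @param mask binary mask.
#' @return list with `class` (factor level `I..IV`) and `probabilities`
#'   (named, summing to 1).
#' @export
classify_mask <- function(classifier, mask) {
  stopifnot(inherits(classifier, "cnn_classifier"))
  if (!is_binary_mask(mask)) stop("mask must be binary (0/1)")
  sz <- classifier$cfg$input_size
  m <- resize_mask(mask, c(sz, sz))
  x <- array(m, c(sz, sz, 1L, 1L))
  p <- drop(softmax_cols(classifier$net$forward(x, train = FALSE)))
  names(p) <- birads_levels
  list(class = factor(birads_levels[which.max(p)], levels = birads_levels),
       probabilities = p)
}

#' Save / load a CNN classifier checkpoint
#' @param classifier a `cnn_classifier`.
#' @param path `.rds` path.
#' @export
save_classifier <- function(classifier, path) {
  saveRDS(list(version = 1L, cfg = classifier$cfg,
               class_weights = classifier$class_weights,
               params = get_params(classifier$net), log = classifier$log),
          path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  ck <- readRDS(path)
  net <- with_seed(0L, build_cnn(ck$cfg))
  set_params(net, ck$params)
  structure(list(net = net, cfg = ck$cfg, class_weights = ck$class_weights,
                 log = ck$log),
            class = "cnn_classifier")
}
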