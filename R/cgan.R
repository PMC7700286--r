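# ---------------------------------------------------------------------------
# Conditional GAN for dense-tissue segmentation: a U-Net generator mapping a
# mammogram to a soft mask, a patch discriminator judging (image, mask)
# pairs, and the alternating training loop combining the adversarial BCE
# with the configured content loss.
# ---------------------------------------------------------------------------

# channel-wise concat / split of (H,W,C,N) tensors
cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
split_ch <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1):d[3], , drop = FALSE])
}

#' Build the U-Net generator
#'
#' The encoder downsamples with stride-2 convolutions until the bottleneck
#' is 1x1 (`log2(image_size)` stages): the first stage is a 7x7 convolution
#' to `base_channels` feature maps, later stages use 4x4 kernels with the
#' channel schedule `base, 2*base, 4*base, 8*base, 8*base, ...`; the middle
#' stages carry residual blocks.  The decoder mirrors the encoder with
#' nearest-neighbour upsampling and skip concatenation from each encoder
#' stage, ending in a sigmoid so outputs lie in `(0,1)`.  At 256 input the
#' encoder has the full 8 stages and a 1x1x`8*base` bottleneck.
#'
#' @param image_size square input size; must be a power of two >= 16.
#' @param base_channels feature maps of the first stage (64 at full scale;
#'   smaller values give a proportionally thinner network for CPU-scale
#'   runs).
#' @param seed optional seed making the random initialization reproducible.
#' @return generator object of class `cgan_generator` with
#'   `forward(x, train)` / `backward(dout)` and metadata fields.
#' @export
build_generator <- function(image_size, base_channels = 64L, seed = NULL) {
  S <- as.integer(round(log2(image_size)))
  if (2^S != image_size || image_size < 16)
    stop("image_size must be a power of two, minimum 16 (got ", image_size,
         "); the encoder downsamples log2(size) times to a 1x1 bottleneck")
  build <- function() {
    e <- new.env(parent = emptyenv())
    class(e) <- "cgan_generator"
    e$image_size <- as.integer(image_size)
    e$base_channels <- as.integer(base_channels)
    e$stages <- S
    ch <- pmin(base_channels * 2^(seq_len(S) - 1L), base_channels * 8L)
    e$ch <- ch
    e$enc <- vector("list", S)
    e$enc_act <- vector("list", S)
    e$res <- vector("list", S)
    for (i in seq_len(S)) {
      e$enc[[i]] <- if (i == 1L)
        layer_conv(1L, ch[1], 7L, stride = 2L, pad = 3L)
      else layer_conv(ch[i - 1], ch[i], 4L, stride = 2L, pad = 1L)
      e$enc_act[[i]] <- layer_act("lrelu")
      if (i > 1L && i < S) e$res[[i]] <- layer_resblock(ch[i])
    }
    e$dec <- vector("list", S - 1L)
    e$dec_act <- vector("list", S - 1L)
    for (i in seq_len(S - 1L)) { # dec[[i]] consumes skip from stage i
      e$dec[[i]] <- layer_conv(ch[i + 1] + ch[i], ch[i], 3L, 1L, 1L)
      e$dec_act[[i]] <- layer_act("relu")
    }
    e$final_conv <- layer_conv(ch[1], 1L, 3L, 1L, 1L)
    e$final_act <- layer_act("sigmoid")

    e$forward <- function(x, train = TRUE) {
      x <- as_tensor(x)
      enc_out <- vector("list", S)
      h <- x
      for (i in seq_len(S)) {
        h <- e$enc_act[[i]]$forward(e$enc[[i]]$forward(h, train), train)
        if (!is.null(e$res[[i]])) h <- e$res[[i]]$forward(h, train)
        enc_out[[i]] <- h
      }
      e$c_skip <- integer(S - 1L)
      d <- h
      for (i in seq(S - 1L, 1L)) {
        up <- .upsample2_fwd(d)
        e$c_skip[i] <- dim(up)[3]
        d <- e$dec_act[[i]]$forward(e$dec[[i]]$forward(
          cat_ch(up, enc_out[[i]]), train), train)
      }
      out <- e$final_act$forward(e$final_conv$forward(.upsample2_fwd(d), train),
                                 train)
      out
    }

    e$backward <- function(dout) {
      d <- e$final_conv$backward(e$final_act$backward(dout))
      dd <- .upsample2_bwd(d)
      de <- vector("list", S) # gradient arriving at each encoder output
      for (i in seq_len(S - 1L)) {
        g <- e$dec[[i]]$backward(e$dec_act[[i]]$backward(dd))
        parts <- split_ch(g, e$c_skip[i])
        de[[i]] <- parts[[2]]
        dd <- .upsample2_bwd(parts[[1]])
      }
      g <- dd # gradient w.r.t. bottleneck (encoder stage S output)
      for (i in seq(S, 1L)) {
        if (!is.null(de[[i]]) && i < S) g <- g + de[[i]]
        if (!is.null(e$res[[i]])) g <- e$res[[i]]$backward(g)
        g <- e$enc[[i]]$backward(e$enc_act[[i]]$backward(g), need_dx = i > 1L)
      }
      invisible(NULL)
    }
    e
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Build the patch discriminator
#'
#' Five convolutional layers over the channel-concatenated (image, mask)
#' pair: the first uses 64-scaled 3x3 filters with stride 2, then three more
#' downsampling/valid stages, ending in a single-channel score map passed
#' through a sigmoid, so every score lies in `(0,1)`.  A 512 input yields a
#' 62x62 score map.
#'
#' @param image_size square input size, >= 64.
#' @param base_channels channel scale (64 at full scale).
#' @param seed optional seed for reproducible initialization.
#' @return discriminator of class `cgan_discriminator` (a sequential module;
#'   `forward` takes the 2-channel conditioned input).
#' @export
build_discriminator <- function(image_size, base_channels = 64L, seed = NULL) {
  if (image_size < 64) stop("discriminator requires image_size >= 64")
  b <- as.integer(base_channels)
  build <- function() {
    e <- nn_sequential(
      layer_conv(2L, b, 3L, stride = 2L, pad = 1L), layer_act("lrelu"),
      layer_conv(b, 2L * b, 4L, stride = 2L, pad = 1L), layer_act("lrelu"),
      layer_conv(2L * b, 4L * b, 4L, stride = 2L, pad = 1L), layer_act("lrelu"),
      layer_conv(4L * b, 8L * b, 3L, stride = 1L, pad = 0L), layer_act("lrelu"),
      layer_conv(8L * b, 1L, 1L, stride = 1L, pad = 0L), layer_act("sigmoid"))
    class(e) <- c("cgan_discriminator", class(e))
    e$image_size <- as.integer(image_size)
    e$base_channels <- b
    e
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Training configuration of the conditional GAN
#'
#' @param learning_rate Adam learning rate (default 0.0002).
#' @param batch_size images per batch (default 4).
#' @param epochs training epochs (default 200; CPU-scale runs use far
#'   fewer).
#' @param adam_beta1 Adam first-moment decay (default 0.5).
#' @param image_size working square resolution.
#' @param base_channels width scale of both networks.
#' @param seed integer seed governing initialization and shuffling.
#' @return object of class `gan_train_config`.
#' @export
gan_train_config <- function(learning_rate = 2e-4, batch_size = 4L,
                             epochs = 200L, adam_beta1 = 0.5,
                             image_size = 512L, base_channels = 64L,
                             seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), adam_beta1 = adam_beta1,
                 image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 seed = as.integer(seed)),
            class = "gan_train_config")
}

# Assemble list-of-matrices data from a manifest or pass a list through.
cgan_training_data <- function(data, image_size) {
  if (is.data.frame(data)) {
    recs <- data[data$split == "train", , drop = FALSE]
    imgs <- list(); msks <- list()
    for (i in seq_len(nrow(recs))) {
      r <- load_record(recs[i, , drop = FALSE])
      imgs[[i]] <- resize_image(r$image, c(image_size, image_size))
      msks[[i]] <- resize_mask(r$mask, c(image_size, image_size))
    }
    list(images = imgs, masks = msks)
  } else {
    stopifnot(is.list(data$images), is.list(data$masks),
              length(data$images) == length(data$masks))
    data
  }
}

#' Train the conditional GAN
#'
#' Alternates a discriminator step (ascend the adversarial BCE on real and
#' generated pairs) and a generator step (non-saturating adversarial term
#' plus `lambda` times the content loss) per batch, with Adam on both
#' networks and seeded shuffling.  When validation data is given, the mean
#' held-out Dice coefficient is tracked per epoch and the best parameters
#' are restored at the end.
#'
#' @param data either a manifest data.frame (its `train` records are loaded
#'   and resized) or a list with `images` and `masks` lists of matrices.
#' @param loss_cfg a [seg_loss_config()].
#' @param train_cfg a [gan_train_config()].
#' @param val optional validation list with `images` and `masks`.
#' @param verbose print per-epoch losses.
#' @return list of class `cgan_model`: `generator`, `discriminator`,
#'   `loss_cfg`, `train_cfg`, and `log` (data.frame epoch, d_loss, g_adv,
#'   g_content, val_dsc).
#' @export
train_cgan <- function(data, loss_cfg = seg_loss_config("DICE"),
                       train_cfg = gan_train_config(), val = NULL,
                       verbose = FALSE) {
  td <- cgan_training_data(data, train_cfg$image_size)
  if (!is.null(val) && length(val$images) == 0) val <- NULL
  n <- length(td$images)
  if (n == 0) stop("empty training split")
  sz <- train_cfg$image_size
  gen <- build_generator(sz, train_cfg$base_channels,
                         seed = stage_seed(train_cfg$seed, "generator"))
  disc <- build_discriminator(sz, train_cfg$base_channels,
                              seed = stage_seed(train_cfg$seed, "discriminator"))
  opt_g <- opt_adam(gen, lr = train_cfg$learning_rate,
                    beta1 = train_cfg$adam_beta1)
  opt_d <- opt_adam(disc, lr = train_cfg$learning_rate,
                    beta1 = train_cfg$adam_beta1)
  gl <- collect_param_layers(gen); dl <- collect_param_layers(disc)
  eps <- 1e-8
  lam <- loss_cfg$lambda_weight
  B <- train_cfg$batch_size

  make_tensor <- function(lst, idx) {
    out <- array(0, c(sz, sz, 1L, length(idx)))
    for (j in seq_along(idx)) out[, , 1L, j] <- lst[[idx[j]]]
    out
  }

  log_rows <- vector("list", train_cfg$epochs)
  best <- list(dsc = -Inf, params = NULL)

  with_seed(stage_seed(train_cfg$seed, "shuffle"), {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / B)
      ep_d <- ep_adv <- ep_con <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * B + 1L):min(bi * B, n)]
        x <- make_tensor(td$images, idx)
        y <- make_tensor(td$masks, idx)
        fake <- gen$forward(x, train = TRUE)

        # --- discriminator step -----------------------------------------
        zero_grads(dl)
        s_real <- disc$forward(cat_ch(x, y), train = TRUE)
        M <- length(s_real)
        disc$backward(array(-1 / (M * pmax(s_real, eps)), dim(s_real)),
                      need_dx = FALSE)
        s_fake <- disc$forward(cat_ch(x, fake), train = TRUE)
        disc$backward(array(1 / (M * pmax(1 - s_fake, eps)), dim(s_fake)),
                      need_dx = FALSE)
        d_loss <- -(mean(log(pmax(s_real, eps))) +
                      mean(log(pmax(1 - s_fake, eps))))
        opt_d$step()

        # --- generator step (non-saturating + lambda * content) ---------
        zero_grads(gl); zero_grads(dl)
        s_fake2 <- disc$forward(cat_ch(x, fake), train = TRUE)
        g_adv <- -mean(log(pmax(s_fake2, eps)))
        dcat <- disc$backward(array(-1 / (M * pmax(s_fake2, eps)),
                                    dim(s_fake2)), need_dx = TRUE)
        dfake <- split_ch(dcat, 1L)[[2]]
        # content loss: per image, averaged over the batch
        con <- 0
        dcon <- array(0, dim(fake))
        for (j in seq_along(idx)) {
          yj <- y[, , 1L, j]; zj <- fake[, , 1L, j]
          con <- con + content_loss(yj, zj, loss_cfg)
          dcon[, , 1L, j] <- content_loss_grad(yj, zj, loss_cfg)
        }
        con <- con / length(idx)
        dtotal <- dfake + lam * dcon / length(idx)
        gen$backward(dtotal)
        opt_g$step()

        ep_d <- ep_d + d_loss; ep_adv <- ep_adv + g_adv; ep_con <- ep_con + con
      }
      val_dsc <- NA_real_
      if (!is.null(val)) {
        val_dsc <- mean(vapply(seq_along(val$images), function(j) {
          pm <- predict_mask_matrix(gen, val$images[[j]])
          1 - dice_loss(val$masks[[j]], pm)
        }, 0))
        if (val_dsc > best$dsc) best <- list(dsc = val_dsc,
                                             params = get_params(gen))
      }
      log_rows[[ep]] <- data.frame(epoch = ep, d_loss = ep_d / nb,
                                   g_adv = ep_adv / nb, g_content = ep_con / nb,
                                   val_dsc = val_dsc)
      if (verbose)
        message(sprintf("epoch %3d  d=%.4f  g_adv=%.4f  g_con=%.4f  val_dsc=%s",
                        ep, ep_d / nb, ep_adv / nb, ep_con / nb,
                        ifelse(is.na(val_dsc), "-", sprintf("%.3f", val_dsc))))
    }
  })
  if (!is.null(best$params)) set_params(gen, best$params)
  structure(list(generator = gen, discriminator = disc, loss_cfg = loss_cfg,
                 train_cfg = train_cfg,
                 log = do.call(rbind, log_rows)),
            class = "cgan_model")
}

# forward-only soft mask for a plain matrix input
predict_mask_matrix <- function(gen, image) {
  out <- gen$forward(as_tensor(image), train = FALSE)
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Predict a binary dense-tissue mask
#'
#' Runs the generator and binarizes its soft output at `threshold`
#' (strictly greater, so threshold 0 keeps every positive response and the
#' predicted mask shrinks monotonically as the threshold rises).
#'
#' @param model a `cgan_model` from [train_cgan()] (or a bare generator).
#' @param image a [mammogram()] or matrix already standardized to the
#'   model's working size.
#' @param threshold binarization threshold in `[0,1)` (default 0.5).
#' @return binary mask matrix of the input shape.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  gen <- if (inherits(model, "cgan_model")) model$generator else model
  px <- if (inherits(image, "mammogram")) image$pixels else image
  if (!all(dim(px) == gen$image_size))
    stop("image must be standardized to the model size (",
         gen$image_size, "x", gen$image_size, ")")
  soft <- predict_mask_matrix(gen, px)
  (soft > threshold) * 1
}

#' Save a trained cGAN checkpoint
#'
#' Parameters plus both configurations, versioned, written with `saveRDS`.
#'
#' @param model a `cgan_model`.
#' @param path output `.rds` path.
#' @export
save_cgan <- function(model, path) {
  saveRDS(list(version = 1L,
               gen_params = get_params(model$generator),
               disc_params = get_params(model$discriminator),
               loss_cfg = model$loss_cfg, train_cfg = model$train_cfg,
               log = model$log), path)
  invisible(path)
}

#' Load a cGAN checkpoint saved by [save_cgan()]
#' @param path checkpoint path.
#' @return a `cgan_model`.
#' @export
load_cgan <- function(path) {
  ck <- readRDS(path)
  gen <- build_generator(ck$train_cfg$image_size, ck$train_cfg$base_channels,
                         seed = 0L)
  disc <- build_discriminator(ck$train_cfg$image_size,
                              ck$train_cfg$base_channels, seed = 0L)
  set_params(gen, ck$gen_params)
  set_params(disc, ck$disc_params)
  structure(list(generator = gen, discriminator = disc,
                 loss_cfg = ck$loss_cfg, train_cfg = ck$train_cfg,
                 log = ck$log),
            class = "cgan_model")
}
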